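# mmCIF/PDB reading and pre-filters.
#
# mmCIF is parsed by a small category/loop reader: the scan needs the
# assembly-generation categories (pdbx_struct_assembly_gen,
# pdbx_struct_oper_list) and entity_poly sequences, which dedicated
# structure readers on CRAN/Bioconductor do not expose.  Legacy PDB files go
# through bio3d::read.pdb and never carry assembly operators.

WATER_RESNAMES <- c("HOH", "DOD", "WAT")

# ---- CIF tokenizer -----------------------------------------------------

# Tokenize CIF lines: quoted strings become single tokens, ;-delimited
# multi-line text fields become single tokens, full/inline comments dropped.
cif_tokenize <- function(lines) {
  tokens <- vector("list", length(lines))
  in_text <- FALSE
  buf <- character()
  k <- 0L
  for (ln in lines) {
    if (in_text) {
      if (startsWith(ln, ";")) {
        in_text <- FALSE
        k <- k + 1L
        tokens[[k]] <- paste(buf, collapse = "\n")
      } else {
        buf <- c(buf, ln)
      }
      next
    }
    if (startsWith(ln, ";")) {
      in_text <- TRUE
      buf <- sub("^;", "", ln)
      next
    }
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    toks <- tryCatch(
      scan(text = ln, what = character(), quote = "'\"",
           comment.char = "#", quiet = TRUE),
      error = function(e) {
        abort(sprintf("malformed CIF line: %s", ln),
              class = "neiss_parse_error")
      }
    )
    if (length(toks)) {
      idx <- k + seq_along(toks)
      tokens[idx] <- as.list(toks)
      k <- k + length(toks)
    }
  }
  if (in_text) {
    abort("unterminated ;-delimited text field", class = "neiss_parse_error")
  }
  unlist(tokens[seq_len(k)], use.names = FALSE)
}

# Parse tokens into a named list of data frames, one per category.
cif_parse <- function(lines) {
  toks <- cif_tokenize(lines)
  n <- length(toks)
  cats <- list()
  add_pairs <- function(cats, tags, values) {
    for (j in seq_along(tags)) {
      parts <- strsplit(sub("^_", "", tags[j]), ".", fixed = TRUE)[[1]]
      cat_name <- parts[1]
      item <- paste(parts[-1], collapse = ".")
      row <- cats[[cat_name]]
      if (is.null(row)) row <- list()
      row[[item]] <- values[j]
      cats[[cat_name]] <- row
    }
    cats
  }
  i <- 1L
  while (i <= n) {
    tok <- toks[i]
    if (identical(tok, "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(toks[i], "_")) {
        tags <- c(tags, toks[i])
        i <- i + 1L
      }
      if (!length(tags)) abort("loop_ without tags", class = "neiss_parse_error")
      vals <- character()
      while (i <= n && !startsWith(toks[i], "_") &&
             !toks[i] %in% c("loop_", "stop_") &&
             !startsWith(toks[i], "data_")) {
        vals <- c(vals, toks[i])
        i <- i + 1L
      }
      if (length(vals) %% length(tags) != 0) {
        abort(sprintf("ragged loop for %s", tags[1]),
              class = "neiss_parse_error")
      }
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      parts <- strsplit(sub("^_", "", tags), ".", fixed = TRUE)
      cat_name <- parts[[1]][1]
      items <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- items
      cats[[cat_name]] <- df
    } else if (startsWith(tok, "_")) {
      if (i + 1L > n) abort(sprintf("tag %s without value", tok),
                            class = "neiss_parse_error")
      cats <- add_pairs(cats, tok, toks[i + 1L])
      i <- i + 2L
    } else {
      i <- i + 1L  # data_/global_/stop_ headers
    }
  }
  lapply(cats, function(x) {
    if (is.data.frame(x)) x else as.data.frame(x, stringsAsFactors = FALSE)
  })
}

cif_col <- function(df, name, default = NA_character_) {
  if (!is.null(df) && name %in% names(df)) df[[name]] else rep(default, max(1L, nrow(df)))
}

cif_na <- function(x) ifelse(x %in% c("?", "."), NA_character_, x)

# ---- file-level gates --------------------------------------------------

#' File-size gate
#'
#' Returns `TRUE` when the input file is strictly smaller than the
#' configured limit (default 10 MB).  Oversized files are meant to be
#' skipped, not parsed; this mirrors the screening protocol's guard against
#' viruses and similarly large assemblies.
#'
#' @param source Path to a structure file.
#' @param config A [scan_config()].
#' @return Logical scalar; `FALSE` comes with a message, never an error.
#' @examples
#' f <- tempfile(); writeLines("x", f)
#' check_size_gate(f, scan_config())
#' @export
check_size_gate <- function(source, config = scan_config()) {
  sz <- suppressWarnings(file.size(source))
  if (is.na(sz)) return(TRUE)  # missing files are diagnosed at parse time
  ok <- sz < config$max_file_bytes
  if (!ok) {
    inform(sprintf("skipping %s: %d bytes >= size gate %d",
                   basename(source), sz, config$max_file_bytes))
  }
  ok
}

#' Fetch a structure by PDB accession
#'
#' Downloads the mmCIF file for a 4-character PDB accession into a cache
#' directory and returns its path.  Requires network access.
#'
#' @param accession 4-character PDB id, e.g. `"4zgy"`.
#' @param cache_dir Directory to store the downloaded file.
#' @param timeout Download timeout in seconds.
#' @return Path to the cached mmCIF file.
#' @export
fetch_structure <- function(accession, cache_dir = tempdir(), timeout = 60) {
  accession <- tolower(accession)
  if (!grepl("^[0-9][a-z0-9]{3}$", accession)) {
    abort(sprintf("'%s' is not a valid PDB accession", accession))
  }
  dest <- file.path(cache_dir, paste0(accession, ".cif"))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.cif", accession)
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) {
                       if (file.exists(dest)) unlink(dest)
                       abort(sprintf("could not fetch %s: %s", accession,
                                     conditionMessage(e)),
                             class = "neiss_fetch_error")
                     })
  if (!identical(status, 0L) || !file.exists(dest)) {
    abort(sprintf("could not fetch %s", accession), class = "neiss_fetch_error")
  }
  dest
}

# ---- parsing -----------------------------------------------------------

read_lines_any <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    readLines(con, warn = FALSE)
  } else {
    readLines(path, warn = FALSE)
  }
}

#' Read a structure file
#'
#' Parses a PDBx/mmCIF (`.cif`, `.cif.gz`) or legacy PDB (`.pdb`, `.ent`,
#' optionally gzipped) file into a `neiss_structure`: an atom table
#' (hydrogens and waters removed, alternate locations resolved to the
#' highest-occupancy conformer), polymer entity sequences, and — for mmCIF —
#' the deposited biological-assembly definitions and operator matrices.
#' Coordinate models beyond `config$max_models` are dropped in file order.
#'
#' @param source Path to a structure file.
#' @param config A [scan_config()].
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @return A list of class `neiss_structure` with elements `structure_id`,
#'   `atoms` (tibble), `entities` (tibble), `assembly_gen` (tibble), `opers`
#'   (named list of 4x4 matrices), `source_format`, `file_bytes`,
#'   `n_models_total`.
#' @examples
#' cif <- make_toy_complex(distance = 3.5)
#' f <- tempfile(fileext = ".cif"); writeLines(cif, f)
#' s <- read_structure(f)
#' s$entities
#' @export
read_structure <- function(source, config = scan_config(), format = "auto") {
  if (!file.exists(source)) {
    abort(sprintf("file not found: %s", source), class = "neiss_parse_error")
  }
  if (identical(format, "auto")) {
    format <- if (grepl("\\.(pdb|ent)(\\.gz)?$", source, ignore.case = TRUE)) "pdb" else "mmcif"
  }
  out <- if (format == "pdb") {
    read_structure_pdb(source, config)
  } else {
    read_structure_mmcif(source, config)
  }
  if (nrow(out$atoms) == 0 || nrow(out$entities) == 0) {
    abort(sprintf("%s contains no polymer chains", out$structure_id),
          class = "neiss_empty_structure")
  }
  out
}

finalize_atoms <- function(atoms, config) {
  atoms <- atoms %>%
    filter(!element %in% c("H", "D"), !resname %in% WATER_RESNAMES)
  if (config$map_mse) {
    atoms$resname[atoms$resname == "MSE"] <- "MET"
  }
  # model cap: keep the first max_models in file order
  keep_models <- unique(atoms$model)[seq_len(min(length(unique(atoms$model)),
                                                 config$max_models))]
  n_total <- length(unique(atoms$model))
  atoms <- atoms %>% filter(model %in% keep_models)
  # altloc: highest occupancy wins, ties to the lexicographically first id
  atoms <- atoms %>%
    mutate(.idx = row_number()) %>%
    group_by(model, label_asym, auth_seq, ins, atom) %>%
    arrange(desc(occupancy), altloc, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.idx) %>%
    select(-".idx")
  list(atoms = atoms, n_models_total = n_total)
}

derive_entities <- function(atoms) {
  # one entity per distinct polymer sequence (legacy PDB has no entity ids)
  seqs <- atoms %>%
    filter(model == atoms$model[1]) %>%
    distinct(label_asym, auth_seq, ins, resname, .keep_all = FALSE) %>%
    group_by(label_asym) %>%
    summarise(sequence = paste(aa_one(resname[resname %in% names(AA_STANDARD)]),
                               collapse = ""), .groups = "drop")
  uniq <- unique(seqs$sequence)
  seqs$entity_id <- paste0("E", match(seqs$sequence, uniq))
  list(
    chain_entity = seqs %>% select(label_asym, entity_id),
    entities = seqs %>%
      distinct(entity_id, sequence) %>%
      mutate(is_polypeptide = nzchar(sequence)) %>%
      as_tibble()
  )
}

read_structure_mmcif <- function(source, config) {
  lines <- read_lines_any(source)
  cats <- cif_parse(lines)
  as_df <- cats[["atom_site"]]
  if (is.null(as_df)) {
    abort("no atom_site records found", class = "neiss_parse_error")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  atoms <- tibble(
    group = cif_col(as_df, "group_PDB", "ATOM"),
    model = {
      m <- cif_na(cif_col(as_df, "pdbx_PDB_model_num", "1"))
      as.integer(ifelse(is.na(m), 1L, m))
    },
    label_asym = cif_na(cif_col(as_df, "label_asym_id")),
    auth_asym = cif_na(cif_col(as_df, "auth_asym_id")),
    entity_id = cif_na(cif_col(as_df, "label_entity_id")),
    resname = cif_na(cif_col(as_df, "label_comp_id")),
    label_seq = as.integer(cif_na(cif_col(as_df, "label_seq_id"))),
    auth_seq = as.integer(cif_na(cif_col(as_df, "auth_seq_id"))),
    ins = {
      v <- cif_na(cif_col(as_df, "pdbx_PDB_ins_code"))
      ifelse(is.na(v), "", v)
    },
    atom = cif_na(cif_col(as_df, "label_atom_id")),
    altloc = {
      v <- cif_na(cif_col(as_df, "label_alt_id"))
      ifelse(is.na(v), "", v)
    },
    occupancy = {
      v <- num(cif_na(cif_col(as_df, "occupancy")))
      ifelse(is.na(v), 1, v)
    },
    x = num(cif_col(as_df, "Cartn_x")),
    y = num(cif_col(as_df, "Cartn_y")),
    z = num(cif_col(as_df, "Cartn_z")),
    element = toupper(cif_na(cif_col(as_df, "type_symbol")))
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    abort("atom_site with non-numeric coordinates", class = "neiss_parse_error")
  }
  atoms$auth_asym[is.na(atoms$auth_asym)] <- atoms$label_asym[is.na(atoms$auth_asym)]
  atoms$auth_seq[is.na(atoms$auth_seq)] <- atoms$label_seq[is.na(atoms$auth_seq)]
  fin <- finalize_atoms(atoms, config)
  atoms <- fin$atoms

  # entities: prefer entity_poly; fall back to residue-derived sequences
  ep <- cats[["entity_poly"]]
  if (!is.null(ep) && "entity_id" %in% names(ep)) {
    seq_raw <- cif_na(cif_col(ep, "pdbx_seq_one_letter_code_can"))
    if (all(is.na(seq_raw))) seq_raw <- cif_na(cif_col(ep, "pdbx_seq_one_letter_code"))
    type <- cif_na(cif_col(ep, "type"))
    entities <- tibble(
      entity_id = ep$entity_id,
      sequence = gsub("\\s", "", ifelse(is.na(seq_raw), "", seq_raw)),
      is_polypeptide = grepl("polypeptide", type)
    )
    # entity ids present in coordinates but absent from entity_poly are
    # non-polymer (ligand) entities; drop them from the chain stream
    atoms <- atoms %>%
      filter(entity_id %in% entities$entity_id |
               (is.na(entity_id) & group == "ATOM"))
  } else {
    de <- derive_entities(atoms %>% filter(group == "ATOM" | resname == "MSE"))
    atoms <- atoms %>%
      select(-entity_id) %>%
      left_join(de$chain_entity, by = "label_asym")
    entities <- de$entities
  }

  # assembly definitions and operators
  ag <- cats[["pdbx_struct_assembly_gen"]]
  assembly_gen <- if (!is.null(ag)) {
    tibble(
      assembly_id = cif_col(ag, "assembly_id", "1"),
      oper_expression = cif_col(ag, "oper_expression", "1"),
      asym_ids = strsplit(cif_col(ag, "asym_id_list", ""), ",", fixed = TRUE)
    )
  } else {
    tibble(assembly_id = character(), oper_expression = character(),
           asym_ids = list())
  }
  ol <- cats[["pdbx_struct_oper_list"]]
  opers <- list()
  if (!is.null(ol)) {
    for (r in seq_len(nrow(ol))) {
      m <- diag(4)
      for (i in 1:3) {
        for (j in 1:3) {
          m[i, j] <- as.numeric(ol[[sprintf("matrix[%d][%d]", i, j)]][r])
        }
        m[i, 4] <- as.numeric(ol[[sprintf("vector[%d]", i)]][r])
      }
      if (anyNA(m)) {
        abort("non-numeric assembly operator matrix", class = "neiss_parse_error")
      }
      rot <- m[1:3, 1:3]
      if (max(abs(crossprod(rot) - diag(3))) > 1e-4) {
        warn(sprintf("assembly operator %s is not orthonormal", ol$id[r]))
      }
      opers[[ol$id[r]]] <- m
    }
  }

  entry_id <- cats[["entry"]]
  structure_id <- if (!is.null(entry_id) && "id" %in% names(entry_id)) {
    tolower(entry_id$id[1])
  } else {
    sub("\\.(cif)(\\.gz)?$", "", basename(source), ignore.case = TRUE)
  }

  new_structure(structure_id, atoms, entities, assembly_gen, opers,
                "mmcif", file.size(source), fin$n_models_total)
}

read_structure_pdb <- function(source, config) {
  path <- source
  if (grepl("\\.gz$", source)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(read_lines_any(source), path)
    on.exit(unlink(path), add = TRUE)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(sprintf("cannot parse PDB file %s: %s",
                                      basename(source), conditionMessage(e)),
                              class = "neiss_parse_error")
  )
  a <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  per_model <- function(m) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else pdb$xyz
    co <- matrix(xyz, ncol = 3, byrow = TRUE)
    tibble(
      group = a$type,
      model = as.integer(m),
      label_asym = a$chain,
      auth_asym = a$chain,
      entity_id = NA_character_,
      resname = a$resid,
      label_seq = NA_integer_,
      auth_seq = as.integer(a$resno),
      ins = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
      atom = a$elety,
      altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
      occupancy = ifelse(is.na(a$o), 1, a$o),
      x = co[, 1], y = co[, 2], z = co[, 3],
      element = toupper(ifelse(is.na(a$elesy), "", a$elesy))
    )
  }
  atoms <- bind_rows(lapply(seq_len(n_models), per_model))
  atoms <- atoms %>% filter(group == "ATOM" | resname == "MSE")
  fin <- finalize_atoms(atoms, config)
  atoms <- fin$atoms
  de <- derive_entities(atoms)
  atoms <- atoms %>%
    select(-entity_id) %>%
    left_join(de$chain_entity, by = "label_asym")
  inform(sprintf(
    "%s: legacy PDB input; REMARK 350 assemblies are not expanded, using the asymmetric unit",
    basename(source)))
  new_structure(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(source), ignore.case = TRUE),
                atoms, de$entities,
                tibble(assembly_id = character(), oper_expression = character(),
                       asym_ids = list()),
                list(), "pdb", file.size(source), fin$n_models_total)
}

new_structure <- function(structure_id, atoms, entities, assembly_gen, opers,
                          source_format, file_bytes, n_models_total) {
  structure(
    list(
      structure_id = structure_id,
      atoms = as_tibble(atoms),
      entities = as_tibble(entities),
      assembly_gen = as_tibble(assembly_gen),
      opers = opers,
      source_format = source_format,
      file_bytes = as.integer(file_bytes),
      n_models_total = as.integer(n_models_total)
    ),
    class = "neiss_structure"
  )
}

#' @export
print.neiss_structure <- function(x, ...) {
  cat(sprintf("<neiss_structure> %s (%s, %d bytes)\n",
              x$structure_id, x$source_format, x$file_bytes))
  cat(sprintf("  models: %d kept (of %d), atoms: %d, entities: %d, assemblies: %d\n",
              length(unique(x$atoms$model)), x$n_models_total, nrow(x$atoms),
              nrow(x$entities), length(unique(x$assembly_gen$assembly_id))))
  invisible(x)
}
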