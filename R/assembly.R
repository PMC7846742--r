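# Biological-assembly generation: expansion of deposited operator
# expressions (including cartesian products of operator lists) into chain
# instances with transformed coordinates.

# Atoms the distance scan ever measures from/to.
SCAN_ATOMS <- c("N", "CA", "C", "NZ")

# Expand an oper_expression such as "1", "1,2,5-8" or "(1-60)(61)" into a
# list of operator-id vectors (one vector per instance; products apply
# right-to-left, matching the PDBx convention).
expand_oper_expression <- function(expr) {
  expr <- gsub("\\s", "", expr)
  groups <- if (grepl("(", expr, fixed = TRUE)) {
    m <- gregexpr("\\(([^)]*)\\)", expr)[[1]]
    if (m[1] == -1) abort(sprintf("malformed oper_expression '%s'", expr),
                          class = "neiss_assembly_error")
    mapply(function(s, l) substr(expr, s + 1, s + l - 2),
           m, attr(m, "match.length"), SIMPLIFY = TRUE)
  } else {
    expr
  }
  expand_group <- function(g) {
    unlist(lapply(strsplit(g, ",", fixed = TRUE)[[1]], function(tok) {
      if (grepl("^-?[0-9]+-[0-9]+$", tok)) {
        r <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
        as.character(seq(r[1], r[2]))
      } else {
        tok
      }
    }))
  }
  ids <- lapply(groups, expand_group)
  # cartesian product, first group outermost, order deterministic
  combos <- list(character(0))
  for (g in ids) {
    combos <- unlist(lapply(combos, function(c0) lapply(g, function(i) c(c0, i))),
                     recursive = FALSE)
  }
  combos
}

oper_matrix <- function(ids, opers, structure_id) {
  m <- diag(4)
  for (id in ids) {
    if (is.null(opers[[id]])) {
      abort(sprintf("%s: oper_expression references undefined operator '%s'",
                    structure_id, id),
            class = "neiss_assembly_error")
    }
    m <- m %*% opers[[id]]
  }
  m
}

# Residue-level table for one label_asym: one row per resolved residue and
# model, with coordinates of the scan atoms (NA when unresolved).
residue_table <- function(atoms_asym) {
  keys <- atoms_asym %>%
    distinct(model, auth_seq, ins, label_seq, resname) %>%
    mutate(pos = ifelse(!is.na(label_seq), label_seq, auth_seq)) %>%
    arrange(model, pos, ins)
  coords <- atoms_asym %>%
    filter(atom %in% SCAN_ATOMS) %>%
    distinct(model, auth_seq, ins, atom, .keep_all = TRUE) %>%
    select(model, auth_seq, ins, atom, x, y, z) %>%
    tidyr::pivot_wider(names_from = atom, values_from = c(x, y, z),
                       names_glue = "{atom}_{.value}")
  for (a in SCAN_ATOMS) {
    for (ax in c("x", "y", "z")) {
      cn <- paste0(a, "_", ax)
      if (!cn %in% names(coords)) coords[[cn]] <- NA_real_
    }
  }
  keys %>%
    left_join(coords, by = c("model", "auth_seq", "ins")) %>%
    mutate(
      is_standard = resname %in% names(AA_STANDARD),
      label = paste0(aa_one(resname), auth_seq, ins)
    )
}

transform_residues <- function(res, m) {
  if (max(abs(m - diag(4))) == 0) return(res)
  rot <- m[1:3, 1:3]
  tr <- m[1:3, 4]
  for (a in SCAN_ATOMS) {
    cols <- paste0(a, "_", c("x", "y", "z"))
    xyz <- as.matrix(res[, cols])
    res[, cols] <- sweep(xyz %*% t(rot), 2, tr, "+")
  }
  res
}

#' Generate biological assemblies as chain instances
#'
#' Expands every deposited assembly definition: each operator expression is
#' expanded (including cartesian products of operator lists), its 4x4
#' transforms are applied to the affected chains, and one chain instance is
#' produced per (assembly, chain, operator product).  When the structure has
#' no assembly definitions — or `config$assembly_mode = "asymmetric_unit"` —
#' a single pseudo-assembly `"AU"` holds the untransformed chains.  Only
#' polypeptide entities are returned.
#'
#' @param structure A `neiss_structure` from [read_structure()].
#' @param config A [scan_config()].
#' @return A tibble with one row per chain instance: `structure_id`,
#'   `assembly_id`, `label_asym_id`, `auth_asym_id`, `operator_id` (operator
#'   product, `"1"` for identity), `entity_id`, `sequence`, and a `residues`
#'   list-column (one row per resolved residue and model with coordinates of
#'   the backbone atoms N/CA/C and lysine NZ).
#' @examples
#' f <- tempfile(fileext = ".cif")
#' writeLines(make_toy_complex(distance = 3.5), f)
#' build_assemblies(read_structure(f))
#' @export
build_assemblies <- function(structure, config = scan_config()) {
  stopifnot(inherits(structure, "neiss_structure"))
  atoms <- structure$atoms
  poly_entities <- structure$entities %>% filter(is_polypeptide)
  poly_map <- atoms %>%
    filter(entity_id %in% poly_entities$entity_id) %>%
    distinct(label_asym, auth_asym, entity_id)
  if (nrow(poly_map) == 0) {
    abort(sprintf("%s contains no polypeptide chains", structure$structure_id),
          class = "neiss_empty_structure")
  }
  res_tables <- lapply(setNames(poly_map$label_asym, poly_map$label_asym),
                       function(asym) residue_table(atoms %>% filter(label_asym == asym)))
  seq_of <- setNames(poly_entities$sequence, poly_entities$entity_id)

  use_au <- config$assembly_mode == "asymmetric_unit" ||
    nrow(structure$assembly_gen) == 0
  inst <- list()
  add_instance <- function(assembly_id, asym, op_id, m) {
    row <- poly_map[poly_map$label_asym == asym, ]
    if (nrow(row) == 0) return(NULL)  # non-polypeptide asym in asym_id_list
    tibble(
      structure_id = structure$structure_id,
      assembly_id = assembly_id,
      label_asym_id = asym,
      auth_asym_id = row$auth_asym[1],
      operator_id = op_id,
      entity_id = row$entity_id[1],
      sequence = unname(seq_of[row$entity_id[1]]),
      residues = list(transform_residues(res_tables[[asym]], m))
    )
  }
  if (use_au) {
    for (asym in poly_map$label_asym) {
      inst[[length(inst) + 1L]] <- add_instance("AU", asym, "1", diag(4))
    }
  } else {
    for (r in seq_len(nrow(structure$assembly_gen))) {
      def <- structure$assembly_gen[r, ]
      combos <- expand_oper_expression(def$oper_expression)
      for (ids in combos) {
        m <- oper_matrix(ids, structure$opers, structure$structure_id)
        op_id <- paste(ids, collapse = "-")
        for (asym in def$asym_ids[[1]]) {
          inst[[length(inst) + 1L]] <- add_instance(def$assembly_id, asym, op_id, m)
        }
      }
    }
  }
  out <- bind_rows(inst)
  if (nrow(out) == 0) {
    abort(sprintf("%s: assemblies contain no polypeptide chains",
                  structure$structure_id),
          class = "neiss_empty_structure")
  }
  # guard against pathological operator products
  n_atoms <- sum(vapply(out$residues, nrow, 0L)) * length(SCAN_ATOMS)
  if (n_atoms > config$max_assembly_atoms) {
    abort(sprintf("%s: expanded assemblies exceed %d atoms",
                  structure$structure_id, config$max_assembly_atoms),
          class = "neiss_assembly_error")
  }
  dup <- duplicated(out[, c("assembly_id", "label_asym_id", "operator_id")])
  if (any(dup)) {
    abort(sprintf("%s: duplicate chain instance keys", structure$structure_id),
          class = "neiss_assembly_error")
  }
  out
}

#' Keep chain instances with resolved standard residues
#'
#' Drops chain instances (rows of the [build_assemblies()] tibble) without a
#' single resolved standard amino acid, e.g. chains consisting only of
#' non-standard ligand-like residues.
#'
#' @param instances Chain-instance tibble from [build_assemblies()].
#' @return The filtered tibble.
#' @export
extract_polymer_chains <- function(instances) {
  keep <- vapply(instances$residues, function(r) any(r$is_standard), TRUE)
  if (any(!keep)) {
    inform(sprintf("dropped %d chain instance(s) without standard residues",
                   sum(!keep)))
  }
  instances[keep, , drop = FALSE]
}
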