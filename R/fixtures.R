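# Synthetic mmCIF fixtures with exactly known geometry.  Residues use an
# idealized template backbone (local bond geometry is plausible, not
# refined); every coordinate is exactly representable at the 3-decimal
# precision written to file, so requested inter-atom distances survive a
# write/parse round trip bit-exactly.

RESIDUE_TEMPLATE <- list(
  backbone = data.frame(
    atom = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = c(0, 1.458, 2.009, 1.600),
    y = c(0, 0, 1.420, 2.540),
    z = c(0, 0, 0, 0),
    stringsAsFactors = FALSE
  ),
  lys_side = data.frame(
    atom = c("CB", "CG", "CD", "CE", "NZ"),
    element = c("C", "C", "C", "C", "N"),
    x = c(1.2, 1.8, 2.4, 3.0, 3.4),
    y = c(-1.1, -2.1, -3.1, -3.9, -4.6),
    z = c(0.8, 1.5, 2.1, 2.7, 3.2),
    stringsAsFactors = FALSE
  )
)

RES_SPACING <- 3.8  # along x, between residue origins

fixture_chain <- function(seq3, shift = c(0, 0, 0)) {
  rows <- lapply(seq_along(seq3), function(i) {
    res <- RESIDUE_TEMPLATE$backbone
    if (seq3[i] == "LYS") res <- rbind(res, RESIDUE_TEMPLATE$lys_side)
    res$resname <- seq3[i]
    res$auth_seq <- i
    res$x <- res$x + (i - 1) * RES_SPACING + shift[1]
    res$y <- res$y + shift[2]
    res$z <- res$z + shift[3]
    res
  })
  do.call(rbind, rows)
}

chain_atom_xyz <- function(chain, seq_num, atom) {
  r <- chain[chain$auth_seq == seq_num & chain$atom == atom, ]
  c(r$x, r$y, r$z)
}

jitter_chain <- function(chain, protect, sd = 0.05) {
  # protect: data.frame(auth_seq, atom) rows that must stay exact
  key <- paste(chain$auth_seq, chain$atom)
  keep <- key %in% paste(protect$auth_seq, protect$atom)
  n <- sum(!keep)
  chain$x[!keep] <- round(chain$x[!keep] + stats::rnorm(n, 0, sd), 3)
  chain$y[!keep] <- round(chain$y[!keep] + stats::rnorm(n, 0, sd), 3)
  chain$z[!keep] <- round(chain$z[!keep] + stats::rnorm(n, 0, sd), 3)
  chain
}

fixture_cif_lines <- function(structure_id, chains, entities, assembly_gen,
                              opers) {
  # chains: list of lists(label_asym, entity_id, atoms data.frame with model)
  out <- c(sprintf("data_%s", toupper(structure_id)),
           "#",
           sprintf("_entry.id %s", toupper(structure_id)),
           "#",
           "loop_",
           "_entity_poly.entity_id",
           "_entity_poly.type",
           "_entity_poly.pdbx_seq_one_letter_code_can")
  for (i in seq_len(nrow(entities))) {
    out <- c(out, sprintf("%s '%s' %s", entities$entity_id[i],
                          entities$type[i], entities$sequence[i]))
  }
  out <- c(out, "#",
           "loop_",
           "_pdbx_struct_assembly_gen.assembly_id",
           "_pdbx_struct_assembly_gen.oper_expression",
           "_pdbx_struct_assembly_gen.asym_id_list")
  for (i in seq_len(nrow(assembly_gen))) {
    out <- c(out, sprintf("%s '%s' %s", assembly_gen$assembly_id[i],
                          assembly_gen$oper_expression[i],
                          assembly_gen$asym_id_list[i]))
  }
  out <- c(out, "#",
           "loop_",
           "_pdbx_struct_oper_list.id",
           "_pdbx_struct_oper_list.type",
           unlist(lapply(1:3, function(i)
             c(sprintf("_pdbx_struct_oper_list.matrix[%d][1]", i),
               sprintf("_pdbx_struct_oper_list.matrix[%d][2]", i),
               sprintf("_pdbx_struct_oper_list.matrix[%d][3]", i),
               sprintf("_pdbx_struct_oper_list.vector[%d]", i)))))
  for (nm in names(opers)) {
    m <- opers[[nm]]
    vals <- unlist(lapply(1:3, function(i) c(m[i, 1:3], m[i, 4])))
    out <- c(out, paste(nm, "'point symmetry operation'",
                        paste(sprintf("%.10g", vals), collapse = " ")))
  }
  out <- c(out, "#",
           "loop_",
           "_atom_site.group_PDB",
           "_atom_site.id",
           "_atom_site.type_symbol",
           "_atom_site.label_atom_id",
           "_atom_site.label_alt_id",
           "_atom_site.label_comp_id",
           "_atom_site.label_asym_id",
           "_atom_site.label_entity_id",
           "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x",
           "_atom_site.Cartn_y",
           "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id",
           "_atom_site.pdbx_PDB_model_num")
  id <- 0L
  for (ch in chains) {
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      id <- id + 1L
      out <- c(out, sprintf(
        "ATOM %d %s %s . %s %s %s %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %d",
        id, a$element[i], a$atom[i], a$resname[i], ch$label_asym,
        ch$entity_id, a$auth_seq[i], a$x[i], a$y[i], a$z[i],
        a$auth_seq[i], a$resname[i], ch$label_asym, a$model[i]))
    }
  }
  c(out, "#")
}

seq3_to1 <- function(seq3) paste(aa_one(seq3), collapse = "")

#' Generate a toy heterodimer fixture
#'
#' Two short chains of distinct sequence: binder chain A (C-terminal
#' glutamate) and target chain B carrying a lysine whose NZ atom is placed
#' exactly `distance` \eqn{\angstrom}{A} from the binder C-terminal
#' carbonyl carbon.  Optionally a lysine is inserted into the binder chain
#' with its NZ at `self_lysine_distance` from the binder C-terminus, to
#' exercise self-reaction detection.  All backbone atoms are present with
#' idealized local geometry; with a `seed`, non-key atoms receive a small
#' deterministic coordinate jitter.
#'
#' @param distance Exact C-terminal C to target lysine NZ distance in
#'   \eqn{\angstrom}{A}.
#' @param self_lysine_distance Optional exact binder-Ct-to-own-lysine-NZ
#'   distance in \eqn{\angstrom}{A}.
#' @param seed Optional integer; jitters non-key atoms reproducibly.
#' @param structure_id Entry id written into the file.
#' @param format `"mmcif"` or `"pdb"` (legacy PDB text of the same atoms;
#'   no assembly records).
#' @return Character vector of file lines (use [writeLines()]).
#' @examples
#' cif <- make_toy_complex(distance = 3.5)
#' f <- tempfile(fileext = ".cif"); writeLines(cif, f)
#' @export
make_toy_complex <- function(distance = 3.5, self_lysine_distance = NULL,
                             seed = NULL, structure_id = "toyhet",
                             format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  stopifnot(distance > 0)
  seq_a <- if (is.null(self_lysine_distance)) c("ALA", "SER", "GLU") else
    c("ALA", "LYS", "SER", "GLU")
  seq_b <- c("MET", "LYS", "ALA")
  chain_a <- fixture_chain(seq_a)
  ct_c <- chain_atom_xyz(chain_a, length(seq_a), "C")
  if (!is.null(self_lysine_distance)) {
    stopifnot(self_lysine_distance > 0)
    nz_pos <- ct_c + c(0, 0, self_lysine_distance)
    sel <- chain_a$auth_seq == 2 & chain_a$atom == "NZ"
    chain_a$x[sel] <- nz_pos[1]; chain_a$y[sel] <- nz_pos[2]; chain_a$z[sel] <- nz_pos[3]
  }
  chain_b <- fixture_chain(seq_b)
  nz_local <- chain_atom_xyz(chain_b, 2, "NZ")
  shift <- ct_c + c(0, distance, 0) - nz_local
  chain_b$x <- chain_b$x + shift[1]
  chain_b$y <- chain_b$y + shift[2]
  chain_b$z <- chain_b$z + shift[3]
  if (!is.null(seed)) {
    withr::with_seed(seed, {
      prot_a <- data.frame(auth_seq = c(length(seq_a), 2),
                           atom = c("C", "NZ"))
      chain_a <- jitter_chain(chain_a, prot_a)
      chain_b <- jitter_chain(chain_b, data.frame(auth_seq = 2, atom = "NZ"))
    })
  }
  chain_a$model <- 1L
  chain_b$model <- 1L
  chains <- list(list(label_asym = "A", entity_id = "1", atoms = chain_a),
                 list(label_asym = "B", entity_id = "2", atoms = chain_b))
  if (format == "pdb") return(fixture_pdb_lines(chains))
  fixture_cif_lines(
    structure_id, chains,
    entities = data.frame(entity_id = c("1", "2"), type = "polypeptide(L)",
                          sequence = c(seq3_to1(seq_a), seq3_to1(seq_b))),
    assembly_gen = data.frame(assembly_id = "1", oper_expression = "1",
                              asym_id_list = "A,B"),
    opers = list(`1` = diag(4))
  )
}

#' Generate a homodimer-by-operator fixture
#'
#' One deposited chain; assembly 1 applies two operators (identity plus a
#' 180-degree rotation about z with a translation chosen so that the second
#' instance's lysine NZ lies exactly `distance` \eqn{\angstrom}{A} from the
#' first instance's C-terminal carbonyl carbon).  Scanning yields
#' homomeric records between the two symmetry copies.
#'
#' @inheritParams make_toy_complex
#' @return Character vector of mmCIF lines.
#' @export
make_homodimer_fixture <- function(distance = 7.0, seed = NULL,
                                   structure_id = "toyhom") {
  stopifnot(distance > 0)
  seq_a <- c("MET", "LYS", "ALA", "GLU")
  chain_a <- fixture_chain(seq_a)
  if (!is.null(seed)) {
    withr::with_seed(seed, {
      chain_a <- jitter_chain(chain_a, data.frame(auth_seq = c(4, 2),
                                                  atom = c("C", "NZ")))
    })
  }
  ct_c <- chain_atom_xyz(chain_a, 4, "C")
  nz <- chain_atom_xyz(chain_a, 2, "NZ")
  rot <- diag(c(-1, -1, 1))
  tr <- ct_c + c(0, distance, 0) - as.numeric(rot %*% nz)
  op2 <- diag(4)
  op2[1:3, 1:3] <- rot
  op2[1:3, 4] <- tr
  chain_a$model <- 1L
  fixture_cif_lines(
    structure_id,
    list(list(label_asym = "A", entity_id = "1", atoms = chain_a)),
    entities = data.frame(entity_id = "1", type = "polypeptide(L)",
                          sequence = seq3_to1(seq_a)),
    assembly_gen = data.frame(assembly_id = "1", oper_expression = "1,2",
                              asym_id_list = "A"),
    opers = list(`1` = diag(4), `2` = op2)
  )
}

#' Generate a multi-model fixture
#'
#' `n_models` coordinate models of the toy heterodimer; model k places the
#' key C-terminus-to-lysine-NZ distance at exactly `base + k`
#' \eqn{\angstrom}{A}, so the cross-model minimum (and the effect of the
#' model cap) is known by construction.
#'
#' @param n_models Number of coordinate models.
#' @param base Base distance in \eqn{\angstrom}{A}; model k sits at
#'   `base + k`.
#' @inheritParams make_toy_complex
#' @return Character vector of mmCIF lines.
#' @export
make_multimodel_fixture <- function(n_models = 12, base = 3.0, seed = NULL,
                                    structure_id = "toymm") {
  stopifnot(n_models >= 1)
  seq_a <- c("ALA", "SER", "GLU")
  seq_b <- c("MET", "LYS", "ALA")
  models_a <- list()
  models_b <- list()
  for (m in seq_len(n_models)) {
    chain_a <- fixture_chain(seq_a)
    ct_c <- chain_atom_xyz(chain_a, 3, "C")
    chain_b <- fixture_chain(seq_b)
    nz_local <- chain_atom_xyz(chain_b, 2, "NZ")
    shift <- ct_c + c(0, base + m, 0) - nz_local
    chain_b$x <- chain_b$x + shift[1]
    chain_b$y <- chain_b$y + shift[2]
    chain_b$z <- chain_b$z + shift[3]
    if (!is.null(seed)) {
      withr::with_seed(seed + m, {
        chain_a <- jitter_chain(chain_a, data.frame(auth_seq = 3, atom = "C"))
        chain_b <- jitter_chain(chain_b, data.frame(auth_seq = 2, atom = "NZ"))
      })
    }
    chain_a$model <- m
    chain_b$model <- m
    models_a[[m]] <- chain_a
    models_b[[m]] <- chain_b
  }
  fixture_cif_lines(
    structure_id,
    list(list(label_asym = "A", entity_id = "1",
              atoms = do.call(rbind, models_a)),
         list(label_asym = "B", entity_id = "2",
              atoms = do.call(rbind, models_b))),
    entities = data.frame(entity_id = c("1", "2"), type = "polypeptide(L)",
                          sequence = c(seq3_to1(seq_a), seq3_to1(seq_b))),
    assembly_gen = data.frame(assembly_id = "1", oper_expression = "1",
                              asym_id_list = "A,B"),
    opers = list(`1` = diag(4))
  )
}

fixture_pdb_lines <- function(chains) {
  out <- character()
  id <- 0L
  for (ch in chains) {
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      id <- id + 1L
      name_fmt <- if (nchar(a$atom[i]) < 4) sprintf(" %-3s", a$atom[i]) else a$atom[i]
      out <- c(out, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        id, name_fmt, a$resname[i], ch$label_asym, a$auth_seq[i],
        a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]))
    }
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d",
                          id + 1L, a$resname[nrow(a)], ch$label_asym,
                          a$auth_seq[nrow(a)]))
  }
  c(out, "END")
}
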