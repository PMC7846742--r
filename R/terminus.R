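# C-terminal and target-residue definitions and the atom-pair priority
# fallback.  The C-terminus of a chain is its last *resolved* standard
# residue (not the sequence terminus); targets are the first resolved
# standard residue (alpha-amine) and every lysine (epsilon-amine, atom NZ).
# The alpha-amine of the first residue is its backbone nitrogen, exposed
# under the name "aN".

# priority fallback order, most preferred first
PRIORITY_LYSINE <- list(
  c("C", "NZ"), c("CA", "NZ"), c("N", "NZ"),
  c("C", "CA"), c("CA", "CA"), c("N", "CA"),
  c("C", "N"), c("CA", "N"), c("N", "N")
)
PRIORITY_NTERM <- list(
  c("C", "aN"), c("CA", "aN"), c("N", "aN"),
  c("C", "CA"), c("CA", "CA"), c("N", "CA")
)

atom_coord_cols <- function(atom) {
  base <- if (atom == "aN") "N" else atom
  paste0(base, "_", c("x", "y", "z"))
}

atom_xyz <- function(row, atom) {
  as.numeric(row[1, atom_coord_cols(atom)])
}

atom_available <- function(row, atom) {
  !anyNA(row[1, atom_coord_cols(atom)])
}

residues_for_model <- function(chain, model_num) {
  res <- if (is.data.frame(chain) && "residues" %in% names(chain)) {
    chain$residues[[1]]
  } else {
    chain
  }
  res[res$model == model_num, , drop = FALSE]
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors in \eqn{\angstrom}{A}.
#' @return Distance in \eqn{\angstrom}{A}.
#' @examples
#' euclidean(c(0, 0, 0), c(3, 4, 0))
#' @export
euclidean <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("non-finite coordinates")
  }
  sqrt(sum((a - b)^2))
}

#' Find the C-terminal residue of a chain instance
#'
#' The last resolved standard amino acid of the chain, with whichever of the
#' backbone atoms C, CA, N are resolved.  Trailing non-standard residues are
#' skipped.
#'
#' @param chain One row of the [build_assemblies()] tibble (or its residue
#'   table directly).
#' @param model Coordinate model number.
#' @return One-row tibble of the residue with an `available_atoms`
#'   list-column, or a zero-row tibble if the chain has no standard residue
#'   in that model.
#' @export
find_c_terminal <- function(chain, model = 1L) {
  res <- residues_for_model(chain, model)
  res <- res[res$is_standard, , drop = FALSE]
  if (nrow(res) == 0) return(res)
  res <- res[order(res$pos, res$ins), , drop = FALSE]
  ct <- res[nrow(res), , drop = FALSE]
  ct$available_atoms <- list(c("C", "CA", "N")[vapply(c("C", "CA", "N"),
                                                      atom_available,
                                                      TRUE, row = ct)])
  ct
}

#' Find target residues of a chain instance
#'
#' Targets are the first resolved standard residue of the chain (kind
#' `n_terminus`, or `n_terminal_lysine` if it is a lysine) plus every other
#' lysine (kind `lysine`).  Target atoms are the lysine side-chain NZ, the
#' first residue's alpha-amine `aN` (its backbone nitrogen), and the
#' backbone fallback atoms CA and N.
#'
#' @inheritParams find_c_terminal
#' @return Tibble with one row per target site: residue columns plus `kind`
#'   and an `available_atoms` list-column.
#' @export
find_targets <- function(chain, model = 1L) {
  res <- residues_for_model(chain, model)
  res <- res[res$is_standard, , drop = FALSE]
  if (nrow(res) == 0) return(res)
  res <- res[order(res$pos, res$ins), , drop = FALSE]
  first <- res[1, , drop = FALSE]
  first$kind <- if (first$resname == "LYS") "n_terminal_lysine" else "n_terminus"
  lys <- res[-1, , drop = FALSE]
  lys <- lys[lys$resname == "LYS", , drop = FALSE]
  if (nrow(lys)) lys$kind <- "lysine"
  out <- bind_rows(first, lys)
  out$available_atoms <- lapply(seq_len(nrow(out)), function(i) {
    row <- out[i, , drop = FALSE]
    cand <- switch(row$kind,
      lysine = c("NZ", "CA", "N"),
      n_terminus = c("aN", "CA"),
      n_terminal_lysine = c("NZ", "aN", "CA")
    )
    cand[vapply(cand, atom_available, TRUE, row = row)]
  })
  out
}

#' All available atom-pair distances between a C-terminus and a target
#'
#' One entry per available (source, target) atom combination drawn from
#' \{C, CA, N\} on the C-terminal residue and the kind-dependent target atom
#' set.  Missing atoms simply produce no entry.
#'
#' @param ct One-row tibble from [find_c_terminal()].
#' @param target One-row tibble from [find_targets()].
#' @return Tibble with columns `source_atom`, `target_atom`, `distance`.
#' @export
all_pair_distances <- function(ct, target) {
  src <- ct$available_atoms[[1]]
  tgt <- target$available_atoms[[1]]
  if (!length(src) || !length(tgt)) {
    return(tibble(source_atom = character(), target_atom = character(),
                  distance = numeric()))
  }
  grid <- expand.grid(source_atom = src, target_atom = tgt,
                      stringsAsFactors = FALSE)
  grid$distance <- vapply(seq_len(nrow(grid)), function(i) {
    euclidean(atom_xyz(ct, grid$source_atom[i]),
              atom_xyz(target, grid$target_atom[i]))
  }, 0)
  as_tibble(grid)
}

#' Select the primary atom pair by the priority fallback order
#'
#' The primary distance for a (C-terminus, target) pair is the first
#' *available* entry of a fixed priority list, not the minimum over pairs.
#' For lysine targets the order is C–NZ, CA–NZ, N–NZ, then backbone
#' fallbacks C–CA, CA–CA, N–CA, C–N, CA–N, N–N.  For plain N-terminal
#' targets NZ is replaced by the alpha-amine `aN` and the `*–N` entries are
#' absent (the first residue's backbone N *is* the alpha-amine).  For an
#' N-terminal lysine, each of the first three ranks pairs the source atom
#' with whichever of `aN`/NZ is available and — if both — gives the shorter
#' distance (exact ties resolve to `aN`).
#'
#' @inheritParams all_pair_distances
#' @return One-row tibble `source_atom`, `target_atom`, `distance`,
#'   `priority_rank`, or a zero-row tibble when no pair is available.
#' @export
select_primary_pair <- function(ct, target) {
  src_avail <- ct$available_atoms[[1]]
  tgt_avail <- target$available_atoms[[1]]
  empty <- tibble(source_atom = character(), target_atom = character(),
                  distance = numeric(), priority_rank = integer())
  if (!length(src_avail) || !length(tgt_avail)) return(empty)
  hit <- function(s, t, rank) {
    tibble(source_atom = s, target_atom = t,
           distance = euclidean(atom_xyz(ct, s), atom_xyz(target, t)),
           priority_rank = as.integer(rank))
  }
  if (target$kind == "n_terminal_lysine") {
    for (rank in 1:3) {
      s <- c("C", "CA", "N")[rank]
      if (!s %in% src_avail) next
      cand <- intersect(c("aN", "NZ"), tgt_avail)
      if (!length(cand)) next
      d <- vapply(cand, function(t) euclidean(atom_xyz(ct, s), atom_xyz(target, t)), 0)
      return(hit(s, cand[which.min(d)], rank))  # tie -> aN (listed first)
    }
    fallback <- list(c("C", "CA"), c("CA", "CA"), c("N", "CA"))
    for (k in seq_along(fallback)) {
      p <- fallback[[k]]
      if (p[1] %in% src_avail && p[2] %in% tgt_avail) return(hit(p[1], p[2], k + 3L))
    }
    return(empty)
  }
  plist <- if (target$kind == "lysine") PRIORITY_LYSINE else PRIORITY_NTERM
  for (k in seq_along(plist)) {
    p <- plist[[k]]
    if (p[1] %in% src_avail && p[2] %in% tgt_avail) return(hit(p[1], p[2], k))
  }
  empty
}
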