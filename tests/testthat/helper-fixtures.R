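# Helpers: write generator fixtures to temp files, build bare residue rows
# for priority-order tests, and a literal brute-force reference for the
# primary-pair selection.

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".cif")
  writeLines(lines, f)
  f
}

# A one-row residue tibble in the layout produced by build_assemblies()'s
# residue tables.  `coords` is a named list over N/CA/C/NZ; missing names
# stay NA (unresolved).
make_residue_row <- function(coords = list(), resname = "LYS", auth_seq = 10L,
                             pos = 10, model = 1L) {
  row <- tibble::tibble(
    model = model, auth_seq = as.integer(auth_seq), ins = "",
    label_seq = NA_integer_, resname = resname, pos = pos,
    is_standard = resname %in% names(neissdist:::AA_STANDARD),
    label = paste0(ifelse(resname == "LYS", "K", "X"), auth_seq)
  )
  for (a in c("N", "CA", "C", "NZ")) {
    v <- coords[[a]]
    if (is.null(v)) v <- c(NA_real_, NA_real_, NA_real_)
    row[[paste0(a, "_x")]] <- v[1]
    row[[paste0(a, "_y")]] <- v[2]
    row[[paste0(a, "_z")]] <- v[3]
  }
  row
}

make_ct <- function(coords = list(), ...) {
  row <- make_residue_row(coords, ...)
  avail <- c("C", "CA", "N")[!is.na(c(row$C_x, row$CA_x, row$N_x))]
  row$available_atoms <- list(avail)
  row
}

make_target <- function(kind, coords = list(), resname = NULL, ...) {
  if (is.null(resname)) {
    resname <- if (kind == "n_terminus") "ALA" else "LYS"
  }
  row <- make_residue_row(coords, resname = resname, ...)
  row$kind <- kind
  cand <- switch(kind,
    lysine = c("NZ", "CA", "N"),
    n_terminus = c("aN", "CA"),
    n_terminal_lysine = c("NZ", "aN", "CA")
  )
  has <- vapply(cand, function(a) {
    base <- if (a == "aN") "N" else a
    !is.na(row[[paste0(base, "_x")]])
  }, TRUE)
  row$available_atoms <- list(cand[has])
  row
}

# Literal "first available entry of the priority list" reference.  Kept
# deliberately naive and separate from the package's implementation.
oracle_primary <- function(ct, target) {
  coord <- function(row, atom) {
    base <- if (atom == "aN") "N" else atom
    c(row[[paste0(base, "_x")]], row[[paste0(base, "_y")]],
      row[[paste0(base, "_z")]])
  }
  have <- function(row, atom) !anyNA(coord(row, atom))
  dst <- function(s, t) sqrt(sum((coord(ct, s) - coord(target, t))^2))
  if (target$kind == "lysine") {
    lst <- list(c("C", "NZ"), c("CA", "NZ"), c("N", "NZ"),
                c("C", "CA"), c("CA", "CA"), c("N", "CA"),
                c("C", "N"), c("CA", "N"), c("N", "N"))
  } else if (target$kind == "n_terminus") {
    lst <- list(c("C", "aN"), c("CA", "aN"), c("N", "aN"),
                c("C", "CA"), c("CA", "CA"), c("N", "CA"))
  } else {
    # N-terminal lysine: alpha-amine or NZ, whichever is shorter (tie: aN)
    for (k in 1:3) {
      s <- c("C", "CA", "N")[k]
      if (!have(ct, s)) next
      best <- NULL
      for (t in c("aN", "NZ")) {
        if (!have(target, t)) next
        d <- dst(s, t)
        if (is.null(best) || d < best$d) best <- list(t = t, d = d)
      }
      if (!is.null(best)) {
        return(list(source_atom = s, target_atom = best$t, distance = best$d,
                    priority_rank = k))
      }
    }
    lst <- list(c("C", "CA"), c("CA", "CA"), c("N", "CA"))
    for (k in seq_along(lst)) {
      p <- lst[[k]]
      if (have(ct, p[1]) && have(target, p[2])) {
        return(list(source_atom = p[1], target_atom = p[2],
                    distance = dst(p[1], p[2]), priority_rank = k + 3L))
      }
    }
    return(NULL)
  }
  for (k in seq_along(lst)) {
    p <- lst[[k]]
    if (have(ct, p[1]) && have(target, p[2])) {
      return(list(source_atom = p[1], target_atom = p[2],
                  distance = dst(p[1], p[2]), priority_rank = k))
    }
  }
  NULL
}

# Enumerate every atom-availability pattern for a target kind and compare
# select_primary_pair() against the literal reference on random coordinates.
check_priority_oracle <- function(n_draws = 3, seed = 421) {
  set.seed(seed)
  src_atoms <- c("C", "CA", "N")
  tgt_sets <- list(
    lysine = c("NZ", "CA", "N"),
    n_terminus = c("N", "CA"),          # N doubles as the alpha-amine
    n_terminal_lysine = c("NZ", "N", "CA")
  )
  mismatches <- 0L
  total <- 0L
  for (kind in names(tgt_sets)) {
    tgt_atoms <- tgt_sets[[kind]]
    for (smask in seq_len(2^length(src_atoms)) - 1L) {
      for (tmask in seq_len(2^length(tgt_atoms)) - 1L) {
        src_on <- src_atoms[bitwAnd(smask, 2^(seq_along(src_atoms) - 1)) > 0]
        tgt_on <- tgt_atoms[bitwAnd(tmask, 2^(seq_along(tgt_atoms) - 1)) > 0]
        for (rep in seq_len(n_draws)) {
          ct <- make_ct(setNames(lapply(src_on, function(a) round(rnorm(3), 3)),
                                 src_on))
          tg <- make_target(kind,
                            setNames(lapply(tgt_on, function(a) round(rnorm(3) + 5, 3)),
                                     tgt_on))
          got <- select_primary_pair(ct, tg)
          want <- oracle_primary(ct, tg)
          total <- total + 1L
          ok <- if (is.null(want)) {
            nrow(got) == 0
          } else {
            nrow(got) == 1 &&
              got$source_atom == want$source_atom &&
              got$target_atom == want$target_atom &&
              got$priority_rank == want$priority_rank &&
              abs(got$distance - want$distance) < 1e-9
          }
          if (!ok) mismatches <- mismatches + 1L
        }
      }
    }
  }
  list(total = total, mismatches = mismatches)
}
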