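# Full per-structure scan: every (C-terminus, target) combination across
# chain instances, models and assemblies, classified and reduced to
# per-structure minima.

#' Classify a chain-instance pair
#'
#' `intramolecular` when source and target are the same chain instance
#' (same assembly, asym id and operator product); otherwise
#' `intermolecular_homomeric` when the two polymer sequences are identical,
#' else `intermolecular_heteromeric`.
#'
#' @param source,target One-row slices of the [build_assemblies()] tibble.
#' @return One of [distance_categories()].
#' @export
classify_pair <- function(source, target) {
  if (!identical(source$assembly_id, target$assembly_id)) {
    abort("chains from different assemblies cannot be classified")
  }
  same_instance <- identical(source$label_asym_id, target$label_asym_id) &&
    identical(source$operator_id, target$operator_id)
  if (same_instance) return("intramolecular")
  if (identical(source$sequence, target$sequence)) {
    return("intermolecular_homomeric")
  }
  "intermolecular_heteromeric"
}

record_columns <- function() {
  tibble(
    structure_id = character(), assembly_id = character(), model = integer(),
    source_asym = character(), source_auth = character(), source_oper = character(),
    source_label = character(), source_auth_seq = integer(),
    target_asym = character(), target_auth = character(), target_oper = character(),
    target_label = character(), target_auth_seq = integer(), target_pos = numeric(),
    target_kind = character(),
    source_atom = character(), target_atom = character(),
    distance = numeric(), priority_rank = integer(), n_pairs = integer(),
    pairs = list(),
    category = character(), covalent = logical(), same_residue = logical()
  )
}

#' Scan a structure for C-terminus-to-amine distances
#'
#' Runs the complete distance survey on one structure: for every coordinate
#' model (up to the configured cap), every assembly, and every ordered pair
#' of chain instances (including a chain against itself), each target site
#' on the target chain is measured against the source chain's C-terminal
#' residue, and the primary atom pair is selected by the priority order.
#' Records where the primary distance falls below the covalent cutoff are
#' flagged `covalent`; measurements from a C-terminal lysine to itself are
#' flagged `same_residue`.
#'
#' @param structure A `neiss_structure`, or a path to a structure file.
#' @param config A [scan_config()].
#' @return A tibble of distance records in deterministic order (assembly,
#'   model, source chain, target chain, target residue), one row per
#'   measured pair, with the full `all_pair_distances()` table nested in the
#'   `pairs` list-column.
#' @examples
#' f <- tempfile(fileext = ".cif")
#' writeLines(make_toy_complex(distance = 3.5), f)
#' recs <- scan_structure(f)
#' dplyr::filter(recs, category == "intermolecular_heteromeric")
#' @export
scan_structure <- function(structure, config = scan_config()) {
  if (is.character(structure)) structure <- read_structure(structure, config)
  instances <- extract_polymer_chains(build_assemblies(structure, config))
  rows <- list()
  for (asm in unique(instances$assembly_id)) {
    asm_inst <- instances %>% filter(assembly_id == asm)
    models <- sort(unique(unlist(lapply(asm_inst$residues, function(r) unique(r$model)))))
    for (mod in models) {
      for (i in seq_len(nrow(asm_inst))) {
        src <- asm_inst[i, , drop = FALSE]
        ct <- find_c_terminal(src, mod)
        if (nrow(ct) == 0) next
        for (j in seq_len(nrow(asm_inst))) {
          tgt_chain <- asm_inst[j, , drop = FALSE]
          targets <- find_targets(tgt_chain, mod)
          if (nrow(targets) == 0) next
          category <- classify_pair(src, tgt_chain)
          for (t in seq_len(nrow(targets))) {
            target <- targets[t, , drop = FALSE]
            primary <- select_primary_pair(ct, target)
            if (nrow(primary) == 0) next  # no resolved atom pair
            pairs <- all_pair_distances(ct, target)
            same_res <- i == j && identical(ct$auth_seq, target$auth_seq) &&
              identical(ct$ins, target$ins)
            rows[[length(rows) + 1L]] <- tibble(
              structure_id = structure$structure_id,
              assembly_id = asm,
              model = as.integer(mod),
              source_asym = src$label_asym_id,
              source_auth = src$auth_asym_id,
              source_oper = src$operator_id,
              source_label = ct$label,
              source_auth_seq = ct$auth_seq,
              target_asym = tgt_chain$label_asym_id,
              target_auth = tgt_chain$auth_asym_id,
              target_oper = tgt_chain$operator_id,
              target_label = target$label,
              target_auth_seq = target$auth_seq,
              target_pos = target$pos,
              target_kind = target$kind,
              source_atom = primary$source_atom,
              target_atom = primary$target_atom,
              distance = primary$distance,
              priority_rank = primary$priority_rank,
              n_pairs = nrow(pairs),
              pairs = list(pairs),
              category = category,
              covalent = primary$distance < config$covalent_cutoff,
              same_residue = same_res
            )
          }
        }
      }
    }
  }
  if (!length(rows)) return(record_columns())
  bind_rows(rows) %>%
    arrange(assembly_id, model, source_asym, source_oper,
            target_asym, target_oper, target_pos)
}

#' Remove records at covalent-linkage range
#'
#' Drops records whose primary distance is strictly below the covalent
#' cutoff (default 1.6 \eqn{\angstrom}{A}); such distances indicate an
#' existing covalent bond (e.g. ubiquitination), not a candidate reaction
#' geometry.
#'
#' @param records A record tibble from [scan_structure()].
#' @param config A [scan_config()].
#' @return The filtered tibble.
#' @export
filter_covalent <- function(records, config = scan_config()) {
  n0 <- nrow(records)
  out <- records %>% filter(distance >= config$covalent_cutoff)
  if (nrow(out) < n0) {
    inform(sprintf("covalent filter removed %d record(s) < %.2f A",
                   n0 - nrow(out), config$covalent_cutoff))
  }
  out
}

#' Per-structure minimum distances
#'
#' Reduces the record stream of one structure to one minimum per category —
#' taken across assemblies and models — and marks the single overall
#' shortest distance.  Ties break deterministically by (assembly, model,
#' source chain, target residue).
#'
#' @param records Records of a single structure.
#' @param config A [scan_config()].
#' @param include_same_residue Whether `same_residue`-flagged records may
#'   carry minima; defaults to the config flag.
#' @return A tibble with at most one row per category: the minimal record's
#'   identifying columns plus `n_records` and a logical `overall` marking
#'   the overall shortest.
#' @export
aggregate_minima <- function(records, config = scan_config(),
                             include_same_residue = config$include_same_residue) {
  stopifnot(length(unique(records$structure_id)) <= 1)
  if (!include_same_residue) records <- records %>% filter(!same_residue)
  if (nrow(records) == 0) {
    out <- record_columns() %>% select(-"pairs", -"target_pos")
    out$n_records <- integer()
    out$overall <- logical()
    return(out)
  }
  minima <- records %>%
    select(-any_of(c("pairs", "target_pos"))) %>%
    group_by(category) %>%
    arrange(distance, assembly_id, model, source_asym, source_oper,
            target_label, .by_group = TRUE) %>%
    mutate(n_records = n()) %>%
    slice(1) %>%
    ungroup()
  ord <- order(minima$distance, minima$assembly_id, minima$model,
               minima$source_asym, minima$source_oper, minima$target_label)
  minima$overall <- FALSE
  minima$overall[ord[1]] <- TRUE
  minima %>% arrange(category)
}

#' Scan a set of structure files
#'
#' Convenience pipeline: applies the size gate, parses, scans and reduces
#' each file, optionally persisting into a distance store.  Unusable files
#' (size gate, parse failures, no polymer chains) are skipped with a logged
#' reason, never an error.
#'
#' @param paths Structure file paths.
#' @param config A [scan_config()].
#' @param store Optional [neiss_store()] to persist into.
#' @return List with `records`, `summaries` and a `skipped` tibble
#'   (`path`, `reason`).
#' @export
scan_files <- function(paths, config = scan_config(), store = NULL) {
  records <- list()
  summaries <- list()
  skipped <- list()
  for (p in paths) {
    if (!check_size_gate(p, config)) {
      skipped[[length(skipped) + 1L]] <- tibble(path = p, reason = "size_gate")
      next
    }
    res <- tryCatch({
      recs <- scan_structure(p, config)
      list(recs = recs, summ = aggregate_minima(recs, config))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reason <- if (inherits(res, "neiss_empty_structure")) "no_polymer" else "parse_error"
      inform(sprintf("skipping %s: %s (%s)", basename(p), reason,
                     conditionMessage(res)))
      skipped[[length(skipped) + 1L]] <- tibble(path = p, reason = reason)
      next
    }
    records[[length(records) + 1L]] <- res$recs
    summaries[[length(summaries) + 1L]] <- res$summ
  }
  out <- list(
    records = if (length(records)) bind_rows(records) else record_columns(),
    summaries = bind_rows(summaries),
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(path = character(), reason = character())
  )
  if (!is.null(store)) {
    store_persist(store, out$records, out$summaries)
  }
  out
}
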