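# Persistent distance store and the aggregate queries over it: structure
# counts below a cutoff per category, shortest-category counts, minima
# histograms and shortlist export.  The store is a directory of three TSV
# tables (structures, records, summaries) — transparent, diff-able and
# dependency-free — queried through dplyr.

STORE_SCHEMA_VERSION <- 1L

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

record_cols_spec <- function() {
  readr::cols(
    structure_id = "c", assembly_id = "c", model = "i",
    source_asym = "c", source_auth = "c", source_oper = "c",
    source_label = "c", source_auth_seq = "i",
    target_asym = "c", target_auth = "c", target_oper = "c",
    target_label = "c", target_auth_seq = "i", target_kind = "c",
    source_atom = "c", target_atom = "c",
    distance = "d", priority_rank = "i", n_pairs = "i",
    category = "c", covalent = "l", same_residue = "l"
  )
}

#' Open or create a distance store
#'
#' @param path Directory holding the store tables; created if absent.
#' @return An object of class `neiss_store`.
#' @examples
#' st <- neiss_store(file.path(tempdir(), "dist-store"))
#' @export
neiss_store <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    jsonlite::write_json(list(schema_version = STORE_SCHEMA_VERSION),
                         meta_path, auto_unbox = TRUE)
  }
  st <- structure(list(path = path), class = "neiss_store")
  for (tab in c("structures", "records", "summaries")) {
    if (!file.exists(store_table_path(st, tab))) {
      store_write_table(st, tab, store_empty_table(tab))
    }
  }
  st
}

store_table_path <- function(store, table) {
  file.path(store$path, paste0(table, ".tsv"))
}

store_empty_table <- function(table) {
  base <- record_columns() %>% select(-"pairs", -"target_pos")
  switch(table,
    structures = tibble(structure_id = character(), n_records = integer()),
    records = base,
    summaries = {
      base$n_records <- integer()
      base$overall <- logical()
      base
    }
  )
}

store_write_table <- function(store, table, df) {
  readr::write_tsv(df, store_table_path(store, table), progress = FALSE)
}

store_read_table <- function(store, table) {
  spec <- record_cols_spec()
  if (table == "structures") {
    spec <- readr::cols(structure_id = "c", n_records = "i")
  } else if (table == "summaries") {
    spec$cols$n_records <- readr::col_integer()
    spec$cols$overall <- readr::col_logical()
  }
  readr::read_tsv(store_table_path(store, table), col_types = spec,
                  progress = FALSE)
}

#' @export
print.neiss_store <- function(x, ...) {
  s <- store_read_table(x, "structures")
  cat(sprintf("<neiss_store> %s\n  structures: %d\n", x$path, nrow(s)))
  invisible(x)
}

#' Persist scan results
#'
#' Writes records and per-structure summaries into the store.  Persisting
#' is idempotent per structure id: re-scanning a structure replaces its
#' previous rows.  Records referencing a structure with no summary row are
#' rejected to preserve referential integrity.
#'
#' @param store A [neiss_store()].
#' @param records Record tibble from [scan_structure()] (the nested `pairs`
#'   column is dropped on disk).
#' @param summaries Summary tibble from [aggregate_minima()].
#' @param structure_ids Optional extra structure ids to register with zero
#'   records (structures that scanned empty).
#' @return The store, invisibly.
#' @export
store_persist <- function(store, records, summaries, structure_ids = NULL) {
  known <- union(unique(summaries$structure_id), structure_ids)
  dangling <- setdiff(unique(records$structure_id), known)
  if (length(dangling)) {
    abort(sprintf("records reference structures without summaries: %s",
                  paste(dangling, collapse = ", ")))
  }
  records <- records %>% select(-any_of(c("pairs", "target_pos")))
  summaries <- summaries %>% select(-any_of(c("pairs", "target_pos")))
  structures <- tibble(structure_id = known) %>%
    left_join(records %>% group_by(structure_id) %>%
                summarise(n_records = n(), .groups = "drop"),
              by = "structure_id") %>%
    mutate(n_records = ifelse(is.na(n_records), 0L, n_records))

  old_structures <- store_read_table(store, "structures")
  replacing <- intersect(old_structures$structure_id, known)
  if (length(replacing)) {
    warn(sprintf("replacing %d previously scanned structure(s)",
                 length(replacing)))
  }
  drop_known <- function(df) df %>% filter(!structure_id %in% known)
  store_write_table(store, "structures",
                    bind_rows(drop_known(old_structures), structures))
  store_write_table(store, "records",
                    bind_rows(drop_known(store_read_table(store, "records")),
                              records))
  store_write_table(store, "summaries",
                    bind_rows(drop_known(store_read_table(store, "summaries")),
                              summaries))
  invisible(store)
}

check_category <- function(category) {
  if (!category %in% distance_categories()) {
    abort(sprintf("unknown category '%s'", category))
  }
  category
}

# Per-structure minima for one category restricted to a primary atom pair.
# The headline queries consider only primary distances C -> NZ (both atoms
# resolved; for N-terminal lysines this means NZ won over the alpha-amine).
category_minima <- function(store, category, pair_filter = c("C", "NZ"),
                            include_covalent = TRUE) {
  recs <- store_read_table(store, "records") %>%
    filter(category == !!check_category(category), !same_residue)
  if (!is.null(pair_filter)) {
    recs <- recs %>%
      filter(source_atom == pair_filter[1], target_atom == pair_filter[2])
  }
  if (!include_covalent) recs <- recs %>% filter(!covalent)
  recs %>%
    group_by(structure_id) %>%
    arrange(distance, assembly_id, model, source_asym, source_oper,
            target_label, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
}

#' Count structures with a category minimum below a cutoff
#'
#' Counts structures whose per-category minimum distance — by default
#' restricted to records whose primary pair is C to NZ, i.e. C-terminus to
#' lysine epsilon-amine — lies strictly below `cutoff`.
#'
#' @param store A [neiss_store()].
#' @param category One of [distance_categories()].
#' @param cutoff Distance cutoff in \eqn{\angstrom}{A} (strict `<`).
#' @param pair_filter Length-2 character `(source_atom, target_atom)`
#'   restricting which records may carry the minimum, or `NULL` for all.
#' @return Integer count.
#' @export
count_structures_below <- function(store, category, cutoff,
                                   pair_filter = c("C", "NZ")) {
  minima <- category_minima(store, category, pair_filter)
  sum(minima$distance < cutoff)
}

#' Count structures by shortest-overall category
#'
#' Each structure contributes once, to the category of its single overall
#' shortest distance; only structures whose overall shortest is strictly
#' below `cutoff` are counted.
#'
#' @inheritParams count_structures_below
#' @return Named integer vector over all three categories.
#' @export
shortest_category_counts <- function(store, cutoff = Inf) {
  summ <- store_read_table(store, "summaries") %>%
    filter(overall, distance < cutoff)
  counts <- table(factor(summ$category, levels = distance_categories()))
  setNames(as.integer(counts), names(counts))
}

#' Histogram of per-structure category minima
#'
#' Assigns per-structure minima to half-open 1 \eqn{\angstrom}{A} bins
#' \[k, k+1) over \[0, 50); minima at or beyond the range upper bound are
#' excluded.
#'
#' @inheritParams count_structures_below
#' @param category A category or `"all"` for all three.
#' @param config A [scan_config()] supplying range and bin width.
#' @return Tibble `category`, `bin_lower`, `bin_upper`, `count`.
#' @export
minima_histogram <- function(store, category = "all", config = scan_config(),
                             pair_filter = c("C", "NZ")) {
  cats <- if (identical(category, "all")) distance_categories() else check_category(category)
  lo <- config$histogram_range[1]
  hi <- config$histogram_range[2]
  bins <- seq(lo, hi - config$bin_width, by = config$bin_width)
  out <- lapply(cats, function(cc) {
    minima <- category_minima(store, cc, pair_filter) %>%
      filter(distance >= lo, distance < hi)
    idx <- findInterval(minima$distance, c(bins, hi))
    counts <- tabulate(idx, nbins = length(bins))
    tibble(category = cc, bin_lower = bins,
           bin_upper = bins + config$bin_width, count = counts)
  })
  bind_rows(out)
}

#' Export the candidate shortlist
#'
#' Per-structure minimal hits of one category, sorted by ascending
#' distance.  Records at covalent range (`< covalent_cutoff`) and
#' same-residue records are excluded; distances are reported rounded to
#' 0.1 \eqn{\angstrom}{A} (half away from zero).
#'
#' @inheritParams count_structures_below
#' @param category Category to export (default heteromeric).
#' @param config A [scan_config()].
#' @param path Optional TSV output path.
#' @return Tibble of shortlist rows (also written to `path` if given).
#' @export
export_shortlist <- function(store, cutoff = 10,
                             category = "intermolecular_heteromeric",
                             config = scan_config(),
                             pair_filter = c("C", "NZ"),
                             path = NULL) {
  minima <- category_minima(store, category, pair_filter,
                            include_covalent = FALSE)
  out <- minima %>%
    filter(distance < cutoff) %>%
    arrange(distance, structure_id, source_auth) %>%
    mutate(distance = round_half_away(distance, 1)) %>%
    select(structure_id, assembly_id, model,
           binder_chain = source_auth, binder_ct = source_label,
           target_chain = target_auth, target_residue = target_label,
           target_kind, source_atom, target_atom, distance, category)
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}
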