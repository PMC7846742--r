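# Single-complex candidate assessment: rank the target protein's amines by
# primary distance to the binder's C-terminus, and measure the binder's own
# nearest amine (self-reaction / "own-goal" risk).  Steric accessibility of
# the site and linker occlusion of the interface are judgement calls on the
# 3D model and are reported as manual-inspection notes, not computed.

amine_sites <- function(chain, model) {
  # lysine NZ sites plus the alpha-amine of the first resolved residue
  find_targets(chain, model)
}

rank_amines <- function(ct, sites) {
  rows <- lapply(seq_len(nrow(sites)), function(t) {
    primary <- select_primary_pair(ct, sites[t, , drop = FALSE])
    if (nrow(primary) == 0) return(NULL)
    tibble(
      residue = sites$label[t],
      auth_seq = sites$auth_seq[t],
      kind = sites$kind[t],
      source_atom = primary$source_atom,
      target_atom = primary$target_atom,
      distance = primary$distance,
      priority_rank = primary$priority_rank
    )
  })
  out <- bind_rows(rows)
  if (nrow(out)) out <- out %>% arrange(distance, auth_seq)
  out
}

#' Screen one binder/target complex
#'
#' Assesses a single complex for C-terminal anhydride chemistry: all amines
#' of the target chain (every lysine NZ plus the chain's alpha-amine) are
#' ranked by primary distance to the binder chain's C-terminus, and the
#' binder's own nearest amine is measured to flag self-reaction risk.
#'
#' @param structure A `neiss_structure` or a structure file path.
#' @param binder_chain,target_chain Author chain ids of the binder (the
#'   chain whose C-terminus carries the anhydride) and the target.
#' @param assembly Assembly id to analyse; default the first one.
#' @param model Coordinate model number.
#' @param config A [scan_config()].
#' @param target_cutoff Criterion cutoff in \eqn{\angstrom}{A}: the nearest
#'   target amine should lie strictly below it.
#' @param self_cutoff Cutoff below which a binder amine counts as a
#'   self-reaction hazard.
#' @return An object of class `neiss_screen` with the ranked amine table,
#'   the binder self-reaction distance, and criterion flags.  See
#'   [tidy.neiss_screen()], [glance.neiss_screen()],
#'   [autoplot.neiss_screen()].
#' @examples
#' f <- tempfile(fileext = ".cif")
#' writeLines(make_toy_complex(distance = 3.5), f)
#' screen_complex(f, binder_chain = "A", target_chain = "B")
#' @export
screen_complex <- function(structure, binder_chain, target_chain,
                           assembly = NULL, model = 1L,
                           config = scan_config(),
                           target_cutoff = 10, self_cutoff = 10) {
  if (is.character(structure)) structure <- read_structure(structure, config)
  instances <- extract_polymer_chains(build_assemblies(structure, config))
  if (is.null(assembly)) assembly <- instances$assembly_id[1]
  instances <- instances %>% filter(assembly_id == assembly)
  pick <- function(chain_id, role) {
    hit <- instances %>% filter(auth_asym_id == chain_id)
    if (nrow(hit) == 0) {
      abort(sprintf("%s chain '%s' not found in assembly %s (available: %s)",
                    role, chain_id, assembly,
                    paste(unique(instances$auth_asym_id), collapse = ", ")))
    }
    hit[1, , drop = FALSE]  # first operator copy
  }
  binder <- pick(binder_chain, "binder")
  target <- pick(target_chain, "target")
  ct <- find_c_terminal(binder, model)
  if (nrow(ct) == 0 || !length(ct$available_atoms[[1]])) {
    abort(sprintf("binder chain '%s' has no resolved C-terminal atoms",
                  binder_chain))
  }
  ranked <- rank_amines(ct, amine_sites(target, model))
  self_sites <- amine_sites(binder, model)
  # exclude the C-terminal residue itself from self-reaction candidates
  self_sites <- self_sites[!(self_sites$auth_seq == ct$auth_seq &
                               self_sites$ins == ct$ins), , drop = FALSE]
  self_ranked <- if (nrow(self_sites)) rank_amines(ct, self_sites) else self_sites[0, ]
  self_nearest <- if (nrow(self_ranked)) self_ranked[1, , drop = FALSE] else NULL

  structure(
    list(
      structure_id = structure$structure_id,
      assembly_id = assembly,
      model = model,
      binder_chain = binder_chain,
      target_chain = target_chain,
      binder_ct = ct$label,
      ranked = ranked,
      nearest_target = if (nrow(ranked)) ranked[1, , drop = FALSE] else NULL,
      self_nearest = self_nearest,
      target_cutoff = target_cutoff,
      self_cutoff = self_cutoff,
      target_within = nrow(ranked) > 0 && ranked$distance[1] < target_cutoff,
      self_clash = !is.null(self_nearest) && self_nearest$distance < self_cutoff,
      notes = c(
        "steric accessibility of the reactive site: manual inspection required",
        "linker/module occlusion of the binding interface: manual inspection required"
      )
    ),
    class = "neiss_screen"
  )
}

#' Nearest amine on the binder chain to its own C-terminus
#'
#' Minimum primary distance from the binder's C-terminal residue to any
#' amine on the same chain (alpha-amine and lysine NZ), excluding the
#' C-terminal residue itself.
#'
#' @inheritParams screen_complex
#' @param binder_chain Author chain id of the binder.
#' @return One-row tibble (`residue`, `distance`, ...) or `NULL` when the
#'   chain carries no other amine.
#' @export
self_reaction_distance <- function(structure, binder_chain, assembly = NULL,
                                   model = 1L, config = scan_config()) {
  if (is.character(structure)) structure <- read_structure(structure, config)
  instances <- extract_polymer_chains(build_assemblies(structure, config))
  if (is.null(assembly)) assembly <- instances$assembly_id[1]
  instances <- instances %>% filter(assembly_id == assembly)
  binder <- instances %>% filter(auth_asym_id == binder_chain)
  if (nrow(binder) == 0) abort(sprintf("chain '%s' not found", binder_chain))
  binder <- binder[1, , drop = FALSE]
  ct <- find_c_terminal(binder, model)
  if (nrow(ct) == 0) return(NULL)
  sites <- amine_sites(binder, model)
  sites <- sites[!(sites$auth_seq == ct$auth_seq & sites$ins == ct$ins), , drop = FALSE]
  if (nrow(sites) == 0) return(NULL)
  ranked <- rank_amines(ct, sites)
  if (nrow(ranked) == 0) return(NULL)
  ranked[1, , drop = FALSE]
}

#' @export
print.neiss_screen <- function(x, ...) {
  cat(sprintf("<neiss_screen> %s assembly %s, binder %s (Ct %s) -> target %s\n",
              x$structure_id, x$assembly_id, x$binder_chain, x$binder_ct,
              x$target_chain))
  if (!is.null(x$nearest_target)) {
    cat(sprintf("  nearest target amine : %s %s at %.1f A (%s-%s)\n",
                x$nearest_target$residue, x$nearest_target$kind,
                round_half_away(x$nearest_target$distance, 1),
                x$nearest_target$source_atom, x$nearest_target$target_atom))
  } else {
    cat("  nearest target amine : none measurable\n")
  }
  if (!is.null(x$self_nearest)) {
    cat(sprintf("  binder self amine    : %s at %.1f A\n",
                x$self_nearest$residue,
                round_half_away(x$self_nearest$distance, 1)))
  } else {
    cat("  binder self amine    : none\n")
  }
  cat(sprintf("  target within %g A   : %s\n", x$target_cutoff, x$target_within))
  cat(sprintf("  self-clash  < %g A   : %s\n", x$self_cutoff, x$self_clash))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Tidy a screening report
#'
#' One row per ranked amine (target amines plus, when present, the binder's
#' own nearest amine flagged by `chain_role`), distances at full precision.
#'
#' @param x A `neiss_screen`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy neiss_screen
#' @export
tidy.neiss_screen <- function(x, ...) {
  tgt <- x$ranked
  if (nrow(tgt)) tgt$chain_role <- "target"
  if (!is.null(x$self_nearest)) {
    s <- x$self_nearest
    s$chain_role <- "binder_self"
    tgt <- bind_rows(tgt, s)
  }
  tgt$structure_id <- x$structure_id
  tgt %>% select(structure_id, chain_role, dplyr::everything())
}

#' Glance at a screening report
#'
#' @param x A `neiss_screen`.
#' @param ... Unused.
#' @return One-row tibble with the headline quantities and flags.
#' @method glance neiss_screen
#' @export
glance.neiss_screen <- function(x, ...) {
  tibble(
    structure_id = x$structure_id,
    binder_chain = x$binder_chain,
    binder_ct = x$binder_ct,
    target_chain = x$target_chain,
    nearest_residue = if (!is.null(x$nearest_target)) x$nearest_target$residue else NA_character_,
    nearest_distance = if (!is.null(x$nearest_target)) x$nearest_target$distance else NA_real_,
    self_residue = if (!is.null(x$self_nearest)) x$self_nearest$residue else NA_character_,
    self_distance = if (!is.null(x$self_nearest)) x$self_nearest$distance else NA_real_,
    target_within = x$target_within,
    self_clash = x$self_clash
  )
}

#' Plot a screening report
#'
#' Lollipop chart of ranked amine distances with the criterion cutoff.
#'
#' @param object A `neiss_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neiss_screen
#' @export
autoplot.neiss_screen <- function(object, ...) {
  df <- tidy(object)
  df$residue <- factor(df$residue, levels = rev(unique(df$residue)))
  ggplot2::ggplot(df, ggplot2::aes(x = distance, y = residue,
                                   colour = chain_role)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = distance,
                                       yend = residue)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$target_cutoff, linetype = 2) +
    ggplot2::labs(
      x = "primary distance to binder C-terminus (Å)", y = NULL,
      colour = NULL,
      title = sprintf("%s: binder %s (Ct %s) vs target %s",
                      object$structure_id, object$binder_chain,
                      object$binder_ct, object$target_chain)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
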