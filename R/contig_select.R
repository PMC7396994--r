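# Contig filtering, orientation, scoring and the three-round assembly
# orchestration. The amplicon plus strand is G-poor, so G-content both
# orients contigs (a contig failing the threshold is retried as its reverse
# complement) and discards unrelated sequence. All threshold comparisons are
# strict, exactly as printed: G < 15%, prefilter 400 < size < 2300 with
# coverage > 30, satisfactory 2040 < size < 2300.

#' Selection thresholds
#'
#' @param g_max maximal G fraction for an oriented contig (strict, default 0.15).
#' @param prefilter_size open size interval kept at pre-selection
#'   (default (400, 2300)).
#' @param coverage_min minimal mean k-mer coverage (strict >, default 30).
#' @param satisfactory_size open interval a selectable contig must fall in
#'   (default (2040, 2300); the methods-style lower bound 2000 can be set here).
#' @param max_trusted maximal number of top contigs forwarded as trusted
#'   inputs to round 2 (default 5).
#' @param round2_k,round3_k k lists for rounds 2 and 3.
#' @return a `selection_thresholds` object.
#' @export
selection_thresholds <- function(g_max = 0.15,
                                 prefilter_size = c(400L, 2300L),
                                 coverage_min = 30,
                                 satisfactory_size = c(2040L, 2300L),
                                 max_trusted = 5L,
                                 round2_k = c(55L, 77L, 99L, 127L),
                                 round3_k = c(77L, 99L, 127L)) {
  if (g_max <= 0 || g_max >= 1) stop("g_max must be in (0,1)")
  if (satisfactory_size[1] < prefilter_size[1] ||
      satisfactory_size[2] > prefilter_size[2])
    stop("satisfactory window must lie within the prefilter window")
  structure(list(g_max = g_max, prefilter_size = as.integer(prefilter_size),
                 coverage_min = coverage_min,
                 satisfactory_size = as.integer(satisfactory_size),
                 max_trusted = as.integer(max_trusted),
                 round2_k = as.integer(round2_k),
                 round3_k = as.integer(round3_k)),
            class = "selection_thresholds")
}

#' G fraction of a sequence
#'
#' @param seq non-empty ACGT string.
#' @return count of G divided by length.
#' @export
g_fraction <- function(seq) {
  .check_dna(seq, "seq")
  lengths(regmatches(seq, gregexpr("G", seq, fixed = TRUE))) / nchar(seq)
}

#' Orient a contig by the G-content rule
#'
#' Returns the contig as-is when its G fraction is below `g_max`; otherwise
#' its reverse complement is checked against the same criterion. When both
#' strands fail, the rejection carries both G fractions.
#'
#' @param seq contig sequence.
#' @param g_max strict upper bound on the G fraction.
#' @return list with `status` ("kept", "flipped" or "rejected"), `seq`
#'   (oriented sequence or NA), `g_fwd`, `g_rev`.
#' @export
orient_contig <- function(seq, g_max = 0.15) {
  gf <- g_fraction(seq)
  if (gf < g_max) return(list(status = "kept", seq = seq, g_fwd = gf, g_rev = NA_real_))
  rc <- cpp_revcomp(seq)
  gr <- g_fraction(rc)
  if (gr < g_max) return(list(status = "flipped", seq = rc, g_fwd = gf, g_rev = gr))
  list(status = "rejected", seq = NA_character_, g_fwd = gf, g_rev = gr)
}

#' Pre-select contigs by orientation, size and coverage
#'
#' Keeps contigs that orient successfully (G fraction below `g_max` on one
#' strand), have 400 < length < 2300 and mean coverage > 30 (all strict,
#' defaults as printed). Kept contigs are returned with their oriented
#' sequence.
#'
#' @param contigs a `contig_set`.
#' @param thresholds a `selection_thresholds`.
#' @return the filtered, oriented `contig_set`.
#' @export
prefilter_contigs <- function(contigs, thresholds = selection_thresholds()) {
  if (nrow(contigs) == 0L) return(contigs)
  keep <- logical(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    ori <- orient_contig(contigs$seq[i], thresholds$g_max)
    if (ori$status == "rejected") next
    contigs$seq[i] <- ori$seq
    keep[i] <- contigs$length[i] > thresholds$prefilter_size[1] &&
      contigs$length[i] < thresholds$prefilter_size[2] &&
      contigs$mean_cov[i] > thresholds$coverage_min
  }
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank prefiltered contigs
#'
#' Deterministic total order: contigs inside the satisfactory size window
#' first, then higher mean coverage, then longer, then id.
#'
#' @inheritParams prefilter_contigs
#' @return the reordered `contig_set`.
#' @export
rank_contigs <- function(contigs, thresholds = selection_thresholds()) {
  if (nrow(contigs) == 0L) return(contigs)
  inside <- contigs$length > thresholds$satisfactory_size[1] &
    contigs$length < thresholds$satisfactory_size[2]
  out <- contigs[order(-inside, -contigs$mean_cov, -contigs$length, contigs$id), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the first satisfactory contig
#'
#' @param ranked a ranked `contig_set`.
#' @inheritParams prefilter_contigs
#' @return a one-row `contig_set`, or NULL when no contig falls in the
#'   satisfactory window.
#' @export
select_satisfactory <- function(ranked, thresholds = selection_thresholds()) {
  if (nrow(ranked) == 0L) return(NULL)
  ok <- ranked$length > thresholds$satisfactory_size[1] &
    ranked$length < thresholds$satisfactory_size[2]
  if (!any(ok)) return(NULL)
  out <- ranked[which(ok)[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the three-round assembly cascade
#'
#' Round 1 is a plain multi-k assembly. If no satisfactory contig emerges,
#' round 2 reruns the assembly with the top-ranked round-1 contigs (at most
#' `max_trusted`) plus the reference as trusted inputs and the round-2 k
#' list. Round 3 uses k = (77, 99, 127), the prior top contigs as untrusted
#' inputs and the reference alone as trusted. Returning no contig after
#' round 3 is a reportable failure, not an error.
#'
#' @param reads character vector of reads.
#' @param ref an `amplicon_reference` (its plus strand is the trusted
#'   reference input).
#' @param thresholds a `selection_thresholds`.
#' @param params an `assembly_params` (round-1 k list and prune settings).
#' @return list with `contig` (one-row `contig_set` or NULL) and `log`
#'   (a `round_log`).
#' @export
run_assembly_rounds <- function(reads, ref, thresholds = selection_thresholds(),
                                params = assembly_params()) {
  log <- list(rounds_used = 0L, rounds = list())
  best_prior <- character(0)
  do_round <- function(p) {
    contigs <- assemble_multi_k(reads, p)
    pref <- prefilter_contigs(contigs, thresholds)
    ranked <- rank_contigs(pref, thresholds)
    sel <- select_satisfactory(ranked, thresholds)
    list(contigs = contigs, ranked = ranked, sel = sel,
         entry = list(n_contigs = nrow(contigs), n_prefiltered = nrow(pref),
                      selected_id = if (is.null(sel)) NA_character_ else sel$id,
                      reason = if (is.null(sel)) "no contig in satisfactory window"
                               else "selected"))
  }
  for (round in 1:3) {
    p <- params
    if (round == 2L) {
      p$k_list <- thresholds$round2_k
      p$trusted_contigs <- c(head(best_prior, thresholds$max_trusted),
                             ref$plus_seq)
    } else if (round == 3L) {
      p$k_list <- thresholds$round3_k
      p$trusted_contigs <- ref$plus_seq
      p$untrusted_contigs <- head(best_prior, thresholds$max_trusted)
    }
    r <- do_round(p)
    log$rounds_used <- round
    log$rounds[[round]] <- r$entry
    best_prior <- unique(c(r$ranked$seq, best_prior))
    if (!is.null(r$sel)) {
      log$selected <- r$entry$selected_id
      return(list(contig = r$sel, log = structure(log, class = "round_log")))
    }
  }
  list(contig = NULL, log = structure(log, class = "round_log"))
}

#' @export
print.round_log <- function(x, ...) {
  cat("Assembly rounds used:", x$rounds_used, "\n")
  for (i in seq_along(x$rounds)) {
    r <- x$rounds[[i]]
    cat(sprintf("  round %d: %d contigs, %d prefiltered, %s\n", i,
                r$n_contigs, r$n_prefiltered,
                if (is.na(r$selected_id)) r$reason else r$selected_id))
  }
  invisible(x)
}
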