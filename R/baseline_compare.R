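# A deliberately minimal mapping/pileup caller standing in for the standard
# secondary-analysis pipeline, plus the cross-pipeline concordance logic.
# The point of the baseline is to reproduce the documented failure-mode
# class of mapping-based callers on low-complexity amplicons — spurious
# heterozygous SNVs in haploid (male) samples around larger indels — not to
# re-implement any specific mapper or caller.

#' Baseline mapping/pileup parameters
#'
#' @param seed_k exact seed k-mer length (default 31).
#' @param band alignment band half-width around the seeded diagonal
#'   (default 30).
#' @param min_depth minimal depth for a call (default 20).
#' @param het_band allele-fraction interval called heterozygous
#'   (default [0.2, 0.8)).
#' @param hom_min allele fraction at or above which a call is hom/hemi
#'   (default 0.8).
#' @param match,mismatch,gap_open,gap_extend extension alignment scores. The
#'   default gap costs make gaps of roughly 20 bp and above uneconomical
#'   against mismatching through a low-complexity tail, which is the
#'   documented blind spot of standard mapping pipelines on this locus
#'   (large indels are missed, and shifted reads produce artifact
#'   heterozygous SNVs in haploid samples).
#' @return a `baseline_params` object.
#' @export
baseline_params <- function(seed_k = 31L, band = 30L, min_depth = 20L,
                            het_band = c(0.2, 0.8), hom_min = 0.8,
                            match = 1, mismatch = -2, gap_open = -18,
                            gap_extend = -6) {
  stopifnot(het_band[1] > 0, het_band[2] <= hom_min, hom_min <= 1)
  structure(list(seed_k = as.integer(seed_k), band = as.integer(band),
                 min_depth = as.integer(min_depth), het_band = het_band,
                 hom_min = hom_min, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "baseline_params")
}

#' Place a single read on the reference (seed and extend)
#'
#' The best exact k-mer seed diagonal (either strand) is extended by a
#' banded affine-gap alignment of the whole read against the implied
#' reference window. Reads sharing no seed k-mer with the reference stay
#' unplaced.
#'
#' @param read read sequence.
#' @param ref an `amplicon_reference` or plain reference string.
#' @param params a `baseline_params`.
#' @return list with `placed`, `start` (1-based), `strand`, `score`, `ops`
#'   (per-column M/X/I/D string), `read_oriented`.
#' @export
place_read <- function(read, ref, params = baseline_params()) {
  refseq <- if (inherits(ref, "amplicon_reference")) ref$plus_seq else ref
  cpp_place_read(read, refseq, params$seed_k, params$band, params$match,
                 params$mismatch, params$gap_open, params$gap_extend)
}

#' Build a pileup from all reads of a sample
#'
#' @param reads character vector of reads (both mates, any orientation).
#' @inheritParams place_read
#' @return a `pileup`: list with `acgt` (4 x L count matrix), `del`
#'   (per-position deletion counts), `depth` (allele-count sum), insertion
#'   records, and the number of placed reads.
#' @export
build_pileup <- function(reads, ref, params = baseline_params()) {
  refseq <- if (inherits(ref, "amplicon_reference")) ref$plus_seq else ref
  p <- cpp_pileup(reads, refseq, params$seed_k, params$band, params$match,
                  params$mismatch, params$gap_open, params$gap_extend)
  rownames(p$acgt) <- c("A", "C", "G", "T")
  p$depth <- colSums(p$acgt) + p$del
  p$ref_seq <- refseq
  structure(p, class = "pileup")
}

#' Call variants from a pileup by allele-fraction thresholds
#'
#' At positions with depth at least `min_depth`, a non-reference allele with
#' fraction at or above `hom_min` is called hom/hemi (hemizygous in males)
#' and one inside the het band is called heterozygous. Deletions are called
#' the same way (adjacent called deletions merge into one event), as are
#' recurrent identical insertion strings.
#'
#' @param pileup a `pileup` from [build_pileup()].
#' @param params a `baseline_params`.
#' @param sample_sex "male", "female" or "unknown" (controls the hom/hemi
#'   zygosity label).
#' @return list of `variant_call`-like records (variant, zygosity, caller
#'   "baseline", support = allele fraction).
#' @export
pileup_call <- function(pileup, params = baseline_params(),
                        sample_sex = c("unknown", "male", "female")) {
  sample_sex <- match.arg(sample_sex)
  refseq <- pileup$ref_seq
  L <- nchar(refseq)
  depth <- pileup$depth
  hom_lab <- if (sample_sex == "male") "hemizygous" else "homozygous"
  calls <- list()
  add <- function(v, af, dp) {
    calls[[length(calls) + 1L]] <<-
      structure(list(variant = v, caller = "baseline", zygosity = v$zygosity,
                     support = c(af = af, depth = dp),
                     hgvs_c = NA_character_, consequence = NA_character_,
                     p_notation = NA_character_, boundary_warning = FALSE,
                     vcf = NULL, frequency = NA_real_, rsid = NA_character_,
                     flags = character(0)),
                class = "variant_call")
  }
  refbase <- strsplit(refseq, "")[[1]]
  bases <- rownames(pileup$acgt)
  callable <- which(depth >= params$min_depth)
  for (pos in callable) {
    for (b in bases) {
      if (b == refbase[pos]) next
      af <- pileup$acgt[b, pos] / depth[pos]
      zyg <- if (af >= params$hom_min) hom_lab
      else if (af >= params$het_band[1] && af < params$het_band[2]) "heterozygous"
      else NA_character_
      if (!is.na(zyg))
        add(variant(pos, pos, refbase[pos], b, zyg), af, depth[pos])
    }
  }
  # deletions: call per position, then merge adjacent runs of equal zygosity
  dzyg <- rep(NA_character_, L)
  daf <- pileup$del / pmax(depth, 1L)
  ok <- depth >= params$min_depth
  dzyg[ok & daf >= params$hom_min] <- hom_lab
  dzyg[ok & daf >= params$het_band[1] & daf < params$het_band[2]] <- "heterozygous"
  pos <- 1L
  while (pos <= L) {
    if (is.na(dzyg[pos])) { pos <- pos + 1L; next }
    e <- pos
    while (e + 1L <= L && !is.na(dzyg[e + 1L]) && dzyg[e + 1L] == dzyg[pos]) e <- e + 1L
    add(variant(pos, e, substr(refseq, pos, e), "", dzyg[pos]),
        mean(daf[pos:e]), as.integer(mean(depth[pos:e])))
    pos <- e + 1L
  }
  if (length(pileup$ins_pos)) {
    for (i in seq_along(pileup$ins_pos)) {
      p <- pileup$ins_pos[i]
      if (p < 1L || p > L || depth[p] < params$min_depth) next
      af <- pileup$ins_count[i] / depth[p]
      zyg <- if (af >= params$hom_min) hom_lab
      else if (af >= params$het_band[1] && af < params$het_band[2]) "heterozygous"
      else NA_character_
      if (!is.na(zyg))
        add(variant(p + 1L, p, "", pileup$ins_seq[i], zyg), af, depth[p])
    }
  }
  calls
}

#' Flag heterozygous calls in haploid (male) samples
#'
#' A heterozygous call at an X-chromosomal locus in a male is an artifact
#' marker (there is only one allele to call); such calls get a
#' `het_in_male` flag.
#'
#' @param calls list of baseline `variant_call` records.
#' @param sample_sex "male", "female" or "unknown".
#' @return the flagged calls.
#' @export
flag_het_in_haploid <- function(calls, sample_sex = c("unknown", "male", "female")) {
  sample_sex <- match.arg(sample_sex)
  if (sample_sex == "unknown") {
    warning("sample sex unknown; heterozygous-in-haploid flag not applied")
    return(calls)
  }
  if (sample_sex != "male") return(calls)
  lapply(calls, function(x) {
    if (identical(x$zygosity, "heterozygous"))
      x$flags <- union(x$flags, "het_in_male")
    x
  })
}

# left-aligned VCF-style key for cross-pipeline matching
.call_key <- function(call, ref) {
  f <- .vcf_fields(call$variant, ref, ref$plus_seq)
  paste(f$chrom, f$pos, f$ref, f$alt, sep = ":")
}

#' Cross-pipeline concordance table with high/low call quality
#'
#' For every variant observed by either pipeline, tallies the number of
#' samples with a baseline call, how many of those were heterozygous (and
#' heterozygous in males), and the number of samples with an assembly
#' (novel-pipeline) call. Quality is high iff the per-sample presence of the
#' variant is identical in both pipelines across all samples, else low.
#' Matching uses the left-aligned anchored representation so the same edit
#' matches across pipelines regardless of naming.
#'
#' @param baseline_by_sample named list (sample id -> list of baseline calls).
#' @param novel_by_sample named list (sample id -> list of assembly calls).
#' @param sexes named character vector of sample sexes.
#' @param ref the `amplicon_reference`.
#' @return data.frame with one row per variant key.
#' @export
concordance_table <- function(baseline_by_sample, novel_by_sample, sexes, ref) {
  samples <- sort(union(names(baseline_by_sample), names(novel_by_sample)))
  keymat <- function(calls_by_sample) {
    lapply(setNames(samples, samples), function(s) {
      cl <- calls_by_sample[[s]]
      if (is.null(cl)) character(0)
      else unique(vapply(cl, .call_key, character(1), ref = ref))
    })
  }
  bk <- keymat(baseline_by_sample)
  nk <- keymat(novel_by_sample)
  het_keys <- lapply(setNames(samples, samples), function(s) {
    cl <- baseline_by_sample[[s]]
    if (is.null(cl)) character(0)
    else unique(vapply(cl[vapply(cl, function(x) identical(x$zygosity, "heterozygous"),
                                 logical(1))],
                       .call_key, character(1), ref = ref))
  })
  allkeys <- sort(unique(c(unlist(bk), unlist(nk))))
  if (length(allkeys) == 0L)
    return(data.frame(variant_key = character(0), n_baseline = integer(0),
                      n_het = integer(0), n_het_male = integer(0),
                      n_novel = integer(0), quality = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(allkeys, function(k) {
    in_b <- vapply(samples, function(s) k %in% bk[[s]], logical(1))
    in_n <- vapply(samples, function(s) k %in% nk[[s]], logical(1))
    in_het <- vapply(samples, function(s) k %in% het_keys[[s]], logical(1))
    male <- !is.na(sexes[samples]) & sexes[samples] == "male"
    data.frame(variant_key = k, n_baseline = sum(in_b), n_het = sum(in_het),
               n_het_male = sum(in_het & male), n_novel = sum(in_n),
               quality = if (identical(in_b, in_n)) "high" else "low",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
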