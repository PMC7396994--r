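# Synthetic-data generator: ORF15-like low-complexity references and
# paired-end amplicon reads with truth variant sets. Patient reads for the
# real locus are not distributable, so everything downstream is exercised on
# references that emulate its documented properties: ~2.1 kb span, a
# purine-rich Glu/Gly-codon coding strand (hence a G-poor plus strand),
# unique primer-site flanks, an embedded exact tandem repeat, deep paired-end
# 2x151 coverage with a 273 bp mean fragment size and primer-site
# over-representation.

# bases of generated non-coding padding between flank and coding segment
.NONCODING_PAD <- 30L
# anchor c. position of the coding segment start (codon-aligned: 1753 = 3*584+1)
.CODING_ANCHOR <- 1753L
.PRIMER_LEN <- 25L

#' Repeat model for synthetic ORF15-like references
#'
#' @param codon_pool named numeric vector: coding-strand codons and sampling
#'   weights. The default is a Glu/Gly-rich purine mix (no stop codons, one
#'   rare C-bearing codon), which forces the plus strand to be G-poor.
#' @param target_length total reference length in bases (default 2100).
#' @param unique_flank_length length of the random unique flank on each side
#'   housing the primer sites (default 60).
#' @param tandem_block list(unit_length, copies) describing an exact tandem
#'   repeat embedded in the coding body (unit_length must be a multiple of 3),
#'   or NULL for none.
#' @return a `repeat_model` object.
#' @export
repeat_model <- function(codon_pool = c(GAA = 0.30, GAG = 0.30, GGA = 0.15,
                                        AGG = 0.10, AAG = 0.08, GAT = 0.05,
                                        GCA = 0.02),
                         target_length = 2100L,
                         unique_flank_length = 60L,
                         tandem_block = list(unit_length = 27L, copies = 4L)) {
  if (length(codon_pool) == 0L) stop("codon pool must be non-empty")
  if (any(nchar(names(codon_pool)) != 3L)) stop("codon pool entries must be codons")
  if (any(names(codon_pool) %in% c("TAA", "TAG", "TGA")))
    stop("codon pool must not contain stop codons")
  if (target_length < 2L * unique_flank_length + 300L)
    stop("target_length must be at least 2*unique_flank_length + 300")
  if (!is.null(tandem_block)) {
    if (tandem_block$unit_length %% 3L != 0L)
      stop("tandem unit_length must be a multiple of 3 (codon aligned)")
    if (tandem_block$copies < 2L) stop("a tandem block needs >= 2 copies")
  }
  structure(list(codon_pool = codon_pool,
                 target_length = as.integer(target_length),
                 unique_flank_length = as.integer(unique_flank_length),
                 tandem_block = tandem_block),
            class = "repeat_model")
}

#' Synthesize an ORF15-like amplicon reference
#'
#' Builds the coding-strand sequence from the codon pool (plus random unique
#' flanks), embeds the tandem block codon-aligned near the middle of the
#' coding body, terminates the coding segment with a stop codon, and returns
#' the reverse complement as the plus strand (`coding_strand = "minus"`).
#' Deterministic per seed. For the default model the plus-strand G fraction
#' is far below the 7% orientation threshold.
#'
#' @param model a `repeat_model`.
#' @param seed integer seed.
#' @return an `amplicon_reference` with a `"structure"` attribute recording
#'   the coding/intron/utr3 spans and the tandem-block span in coding-sense
#'   coordinates.
#' @export
synthesize_reference <- function(model, seed = 1L) {
  L <- model$target_length
  fl <- model$unique_flank_length
  body_len <- L - 2L * fl
  ncod <- body_len %/% 3L
  pad3 <- body_len - 3L * ncod
  with_seed(seed, {
    flank5 <- paste(sample(c("A", "C", "G", "T"), fl, replace = TRUE), collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), fl + pad3, replace = TRUE), collapse = "")
    codons <- sample(names(model$codon_pool), ncod, replace = TRUE,
                     prob = model$codon_pool)
    tb_span <- NULL
    if (!is.null(model$tandem_block)) {
      uc <- model$tandem_block$unit_length %/% 3L
      cp <- model$tandem_block$copies
      unit <- sample(names(model$codon_pool), uc, replace = TRUE,
                     prob = model$codon_pool)
      first <- ncod %/% 2L - (uc * cp) %/% 2L
      if (first < .NONCODING_PAD / 3L + 2L || first + uc * cp > ncod)
        stop("tandem block does not fit in the coding body")
      codons[first:(first + uc * cp - 1L)] <- rep(unit, cp)
      tb_start <- fl + 3L * (first - 1L) + 1L
      tb_span <- c(tb_start, tb_start + 3L * uc * cp - 1L)
    }
    # transcript layout on the coding-sense sequence:
    #   [flank5 + pad] intron | coding (ends with TAA) | [pad + flank3] utr3
    intron_end <- fl + .NONCODING_PAD
    coding_end <- L - fl - .NONCODING_PAD
    stop_codon_idx <- (coding_end - fl) %/% 3L    # last full codon inside coding
    codons[stop_codon_idx] <- "TAA"
    cseq <- paste0(flank5, paste(codons, collapse = ""), flank3)
    stopifnot(nchar(cseq) == L)
    plus <- cpp_revcomp(cseq)
    ref <- amplicon_reference(
      name = sprintf("synthetic_orf15_like_seed%d", as.integer(seed)),
      plus_seq = plus, chrom = "chrX",
      start = 38144633L, end = 38144633L + L - 1L,
      primer_fwd = c(1L, .PRIMER_LEN), primer_rev = c(L - .PRIMER_LEN + 1L, L),
      coding_strand = "minus")
    attr(ref, "structure") <- list(
      cseq_len = L,
      intron = c(1L, intron_end),
      coding = c(intron_end + 1L, coding_end),
      utr3 = c(coding_end + 1L, L),
      tandem_block = tb_span,
      seed = as.integer(seed))
    ref
  })
}

#' Default transcript coordinate map for a synthesized reference
#'
#' Mirrors the ORF15 situation: the transcript runs on the minus strand of
#' the amplicon; a short intronic stretch (offsets `c.<anchor>-K`) precedes
#' the coding segment (anchored at c.1753), which is followed by the 3'UTR
#' (`c.*N`).
#'
#' @param ref a reference from [synthesize_reference()].
#' @return a `coordinate_map`.
#' @export
default_coordinate_map <- function(ref) {
  st <- attr(ref, "structure")
  if (is.null(st)) stop("reference carries no structure attribute")
  L <- st$cseq_len
  amp <- function(cspan) c(L - cspan[2] + 1L, L - cspan[1] + 1L)
  a_int <- amp(st$intron); a_cod <- amp(st$coding); a_utr <- amp(st$utr3)
  segs <- data.frame(
    amp_start = c(a_utr[1], a_cod[1], a_int[1]),
    amp_end = c(a_utr[2], a_cod[2], a_int[2]),
    kind = c("utr3", "coding", "intron_offset"),
    c_anchor = c(1L, .CODING_ANCHOR, .CODING_ANCHOR),
    stringsAsFactors = FALSE)
  coordinate_map(transcript_id = "SYN-ORF15-LIKE.1", orientation = "opposite",
                 segments = segs)
}

#' Simulation configuration
#'
#' @param coverage mean per-base depth (default 1000).
#' @param read_length read length in bases (default 151).
#' @param fragment_mean,fragment_sd fragment-size distribution, normal
#'   clamped at `read_length` (defaults 273 and 40).
#' @param sub_error_rate per-base substitution error rate (default 0.001).
#' @param indel_error_rate per-base sequencing indel rate (default 0; the
#'   default error model is substitutions only).
#' @param primer_boost multiplicative over-representation of fragments
#'   touching a primer span (default 3).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param allele_ratio fraction of fragments drawn from allele B when diploid.
#' @param quality_char constant Phred quality character (default `"?"`, Q30).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(coverage = 1000, read_length = 151L,
                              fragment_mean = 273, fragment_sd = 40,
                              sub_error_rate = 0.001, indel_error_rate = 0,
                              primer_boost = 3, ploidy = c("haploid", "diploid"),
                              allele_ratio = 0.5, quality_char = "?") {
  ploidy <- match.arg(ploidy)
  stopifnot(coverage > 0, read_length > 0,
            sub_error_rate >= 0, sub_error_rate <= 1,
            indel_error_rate >= 0, indel_error_rate <= 1,
            primer_boost >= 1, allele_ratio >= 0, allele_ratio <= 1)
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 sub_error_rate = sub_error_rate,
                 indel_error_rate = indel_error_rate,
                 primer_boost = primer_boost, ploidy = ploidy,
                 allele_ratio = allele_ratio, quality_char = quality_char),
            class = "simulation_config")
}

.add_sub_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads)
  n <- sum(rl)
  hits <- which(runif(n) < rate)
  if (length(hits) == 0L) return(reads)
  ends <- cumsum(rl)
  ri <- findInterval(hits - 1L, ends) + 1L
  off <- hits - c(0L, ends)[ri]
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hits)) {
    i <- ri[j]; p <- off[j]
    cur <- substr(reads[i], p, p)
    substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
  }
  reads
}

.simulate_allele_frags <- function(allele_seq, n_frag, cfg, primer_len) {
  len <- nchar(allele_seq)
  rl <- cfg$read_length
  fl <- pmin(pmax(round(rnorm(n_frag, cfg$fragment_mean, cfg$fragment_sd)), rl), len)
  # primer boost: draw candidate starts uniformly, then pick one per fragment
  # by exponential races so P(candidate) is proportional to its weight
  cand <- 3L
  st <- 1L + floor(matrix(runif(n_frag * cand), ncol = cand) * (len - fl + 1L))
  touches <- function(s) s <= primer_len | (s + fl - 1L) >= (len - primer_len + 1L)
  w <- matrix(1, n_frag, cand)
  for (j in seq_len(cand)) w[touches(st[, j]), j] <- cfg$primer_boost
  pick <- max.col(-matrix(stats::rexp(n_frag * cand), ncol = cand) / w,
                  ties.method = "first")
  starts <- st[cbind(seq_len(n_frag), pick)]
  frags <- substring(allele_seq, starts, starts + fl - 1L)
  minus <- runif(n_frag) < 0.5
  frags[minus] <- revcomp(frags[minus])
  r1 <- substr(frags, 1L, rl)
  r2 <- revcomp(substring(frags, fl - rl + 1L, fl))
  list(r1 = r1, r2 = r2)
}

#' Simulate a paired-end amplicon sample
#'
#' Applies the truth variant set(s) to the reference, draws clamped-normal
#' fragments with primer-site over-representation, and emits inward-facing
#' 2 x `read_length` mates with substitution errors and constant qualities.
#' The expected number of pairs is `coverage * allele_length / (2 *
#' read_length)`. Fully deterministic per seed.
#'
#' @param ref an `amplicon_reference`.
#' @param truth a `variant_set` (haploid) or list of two (diploid alleles
#'   A and B).
#' @param cfg a `simulation_config`.
#' @param seed integer seed.
#' @param out_dir if non-NULL, gzipped FASTQ pair and a truth YAML record are
#'   written there.
#' @param sample_id sample name used in read names and file names.
#' @return list with `r1`, `r2` (character vectors), `truth`, `n_pairs`, and
#'   file `paths` when written.
#' @export
simulate_sample <- function(ref, truth, cfg = simulation_config(), seed = 1L,
                            out_dir = NULL, sample_id = "sample") {
  if (cfg$ploidy == "diploid") {
    if (!is.list(truth) || length(truth) != 2L)
      stop("diploid simulation needs a list of two variant sets")
    alleles <- lapply(truth, function(v) apply_variant_set(ref$plus_seq, v))
  } else {
    if (!inherits(truth, "variant_set")) truth <- variant_set(truth)
    alleles <- list(apply_variant_set(ref$plus_seq, truth))
  }
  with_seed(seed, {
    mean_len <- mean(nchar(unlist(alleles)))
    n_pairs <- max(1L, round(cfg$coverage * mean_len / (2 * cfg$read_length)))
    n_b <- if (length(alleles) == 2L) round(n_pairs * cfg$allele_ratio) else 0L
    n_per <- if (length(alleles) == 2L) c(n_pairs - n_b, n_b) else n_pairs
    r1 <- character(0); r2 <- character(0)
    for (i in seq_along(alleles)) {
      if (n_per[i] == 0L) next
      fr <- .simulate_allele_frags(alleles[[i]], n_per[i], cfg, .PRIMER_LEN)
      r1 <- c(r1, fr$r1); r2 <- c(r2, fr$r2)
    }
    r1 <- .add_sub_errors(r1, cfg$sub_error_rate)
    r2 <- .add_sub_errors(r2, cfg$sub_error_rate)
    out <- list(r1 = r1, r2 = r2, truth = truth, n_pairs = length(r1),
                sample_id = sample_id)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p1 <- file.path(out_dir, paste0(sample_id, "_R1.fastq.gz"))
      p2 <- file.path(out_dir, paste0(sample_id, "_R2.fastq.gz"))
      ids <- paste0(sample_id, "_", seq_along(r1))
      write_fastq(r1, paste0(ids, "/1"), p1, cfg$quality_char)
      write_fastq(r2, paste0(ids, "/2"), p2, cfg$quality_char)
      pt <- file.path(out_dir, paste0(sample_id, "_truth.yaml"))
      tl <- if (inherits(truth, "variant_set")) list(truth) else truth
      yaml::write_yaml(list(sample_id = sample_id, seed = as.integer(seed),
                            alleles = lapply(tl, function(vs) lapply(vs, function(v)
                              list(start = v$start, end = v$end,
                                   ref = v$ref_allele, alt = v$alt_allele,
                                   kind = v$kind, zygosity = v$zygosity)))),
                       pt)
      out$paths <- c(r1 = p1, r2 = p2, truth = pt)
    }
    out
  })
}

#' Write reads as gzipped FASTQ
#'
#' @param reads character vector of sequences.
#' @param ids read names (without `@`).
#' @param path output path (`.gz` implies gzip).
#' @param quality_char constant quality character.
#' @export
write_fastq <- function(reads, ids, path, quality_char = "?") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  quals <- strrep(quality_char, nchar(reads))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", quals), con)
  invisible(path)
}

#' Read a FASTQ pair into plain character vectors
#'
#' @param r1_path,r2_path FASTQ(.gz) paths.
#' @return list with `r1` and `r2` character vectors.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
    con <- if (grepl("\\.gz$", p)) gzfile(p) else file(p)
    n_lines <- length(readLines(con, warn = FALSE))
    if (n_lines %% 4L != 0L)
      stop("truncated FASTQ: ", p, " has ", n_lines,
           " lines (not a multiple of 4)")
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    as.character(unname(x))
  }
  list(r1 = rd(r1_path), r2 = rd(r2_path))
}

# first codon-aligned coding-sense position >= at with the given codon,
# outside the forbidden span
.find_codon <- function(cseq, st, codon, at, avoid = NULL) {
  cod0 <- st$coding[1]
  p <- cod0 + 3L * ceiling((max(at, cod0) - cod0) / 3)
  while (p + 2L <= st$coding[2]) {
    ok <- substr(cseq, p, p + 2L) == codon
    if (ok && !is.null(avoid)) ok <- p + 2L < avoid[1] || p > avoid[2]
    if (ok) return(p)
    p <- p + 3L
  }
  stop("no ", codon, " codon found after coding-sense position ", at)
}

#' Canonical truth-set catalogue for a synthesized reference
#'
#' One named single-variant truth set per variant class observed at the real
#' locus: a nonsense SNV, 2-bp and 4-bp frameshift deletions, a 2-bp delins,
#' in-frame duplications of 15/21/27 bp inside the tandem block, and a 51-bp
#' insertion. All variants are placed in the coding segment, away from the
#' primer sites, and are expressed in amplicon plus-strand coordinates.
#'
#' @param ref a reference from [synthesize_reference()].
#' @return named list of `variant_set` objects.
#' @export
spike_standard_truthsets <- function(ref) {
  st <- attr(ref, "structure")
  if (is.null(st)) stop("reference carries no structure attribute")
  cseq <- cpp_revcomp(ref$plus_seq)
  tb <- st$tandem_block
  cod0 <- st$coding[1]
  mk <- function(cv) variant_set(.from_coding_space(cseq, cv, "opposite"))
  out <- list()

  # nonsense SNV: GAA -> TAA at the first Glu codon past cod0+120
  p <- .find_codon(cseq, st, "GAA", cod0 + 120L, avoid = tb)
  out$snv <- mk(variant(p, p, "G", "T", "hemizygous"))

  # 2-bp GG deletion (frameshift), mirrors the recurrent delGG class
  gg <- regexpr("GG", substr(cseq, cod0 + 280L, if (is.null(tb)) st$coding[2] else tb[1] - 30L),
                fixed = TRUE)
  if (gg < 0) stop("no GG dinucleotide available for the del2 class")
  s <- cod0 + 280L + gg - 1L
  out$del2 <- mk(variant(s, s + 1L, substr(cseq, s, s + 1L), "", "hemizygous"))

  # 4-bp deletion (frameshift)
  s <- cod0 + 420L
  out$del4 <- mk(variant(s, s + 3L, substr(cseq, s, s + 3L), "", "hemizygous"))

  # 2-bp delins: both bases substituted (transversion map keeps them distinct)
  s <- cod0 + 540L
  rb <- substr(cseq, s, s + 1L)
  out$delins2 <- mk(variant(s, s + 1L, rb, chartr("ACGT", "GTAC", rb), "hemizygous"))

  # in-frame duplications inside the tandem block (3'-terminal sub-segments)
  if (is.null(tb)) stop("dup truth sets require a tandem block in the model")
  for (w in c(15L, 21L, 27L)) {
    dup <- substr(cseq, tb[2] - w + 1L, tb[2])
    out[[paste0("dup", w)]] <- mk(variant(tb[2] + 1L, tb[2], "", dup, "hemizygous"))
  }

  # 51-bp insertion (not a duplication of its 5' context)
  s <- cod0 + 3L * ceiling(1200 / 3)
  ins <- with_seed(920L, paste(sample(c("GAA", "GAG", "GGA", "AGG", "AAG", "GAT"),
                                      17L, replace = TRUE), collapse = ""))
  stopifnot(substr(cseq, s - 51L, s - 1L) != ins)
  out$ins51 <- mk(variant(s, s - 1L, "", ins, "hemizygous"))

  for (vs in out) .validate_against_ref(ref$plus_seq, vs)
  out
}
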