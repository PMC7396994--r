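# Global contig-to-reference alignment and variant calling. SNVs come from
# mismatch columns, indels from gap runs; a maximal run of non-match columns
# containing any gap becomes a single event (del/ins/delins), which is how
# a mismatch adjacent to a gap is reported as one delins. Indels are then
# 3'-shifted on the transcript sense for HGVS and left-aligned on the plus
# strand for VCF — two renderings of the same internal variant.

#' Alignment parameters
#'
#' A gap of length L costs `gap_open + L * gap_extend`; terminal gap runs are
#' free (overlap alignment), which tolerates contigs that overshoot the
#' reference at over-represented primer sites or fall slightly short of its
#' ends. The small gap-extension penalty keeps long indels in repeat tracts
#' contiguous instead of scattering them.
#'
#' @param match,mismatch,gap_open,gap_extend scores (defaults +1, -2, -12,
#'   -0.5).
#' @return an `align_params` object.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = -12,
                         gap_extend = -0.5) {
  if (!(gap_open <= mismatch && mismatch < match)) stop("need gap_open <= mismatch < match")
  if (gap_extend >= 0) stop("gap_extend must be negative")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Optimal affine-gap global (ends-free) alignment
#'
#' @param query pre-oriented contig sequence (the aligner never reverse
#'   complements).
#' @param ref reference plus-strand sequence.
#' @param params an `align_params`.
#' @return a `pairwise_alignment`: `ref_row`, `query_row` (equal-length gapped
#'   strings with no gap/gap column), `score`, `params`.
#' @export
global_align <- function(query, ref, params = align_params()) {
  .check_dna(query, "query"); .check_dna(ref, "ref")
  r <- cpp_global_align(query, ref, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  structure(list(ref_row = r$ref_row, query_row = r$query_row,
                 score = r$score, params = params),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment of", sum(strsplit(x$query_row, "")[[1]] != "-"),
      "bp query vs", sum(strsplit(x$ref_row, "")[[1]] != "-"),
      "bp ref, score", x$score, ">\n")
  invisible(x)
}

#' Call raw variants from a pairwise alignment
#'
#' Maximal runs of non-match columns are segmented: runs without gaps yield
#' one SNV per mismatch column; runs containing any gap yield one event (del
#' if only reference bases, ins if only query bases, delins otherwise).
#' Terminal gap runs (contig overhang or uncovered reference ends) are not
#' called. Coordinates are ungapped reference positions.
#'
#' @param aln a `pairwise_alignment`.
#' @return list of `variant` objects (zygosity unknown).
#' @export
calls_from_alignment <- function(aln) {
  r <- strsplit(aln$ref_row, "")[[1]]
  q <- strsplit(aln$query_row, "")[[1]]
  n <- length(r)
  if (length(q) != n) stop("alignment rows differ in length")
  gap <- r == "-" | q == "-"
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  tail <- n + 1L
  while (tail > 1L && gap[tail - 1L]) tail <- tail - 1L
  refpos <- cumsum(r != "-")
  nonmatch <- r != q
  nonmatch[seq_len(lead)] <- FALSE
  if (tail <= n) nonmatch[tail:n] <- FALSE
  calls <- list()
  i <- lead + 1L
  while (i < tail) {
    if (!nonmatch[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L < tail && nonmatch[j + 1L]) j <- j + 1L
    run <- i:j
    if (!any(gap[run])) {
      for (c0 in run)
        calls[[length(calls) + 1L]] <- variant(refpos[c0], refpos[c0], r[c0], q[c0])
    } else {
      refb <- r[run][r[run] != "-"]
      qryb <- q[run][q[run] != "-"]
      if (length(refb)) {
        s <- refpos[run[which(r[run] != "-")[1L]]]
        e <- s + length(refb) - 1L
        calls[[length(calls) + 1L]] <-
          variant(s, e, paste(refb, collapse = ""), paste(qryb, collapse = ""))
      } else {
        p <- refpos[i]              # position of last ref base before the run
        calls[[length(calls) + 1L]] <-
          variant(p + 1L, p, "", paste(qryb, collapse = ""))
      }
    }
    i <- j + 1L
  }
  calls
}

# ---- consequence classification --------------------------------------------

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

.translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# coding segment span in coding-sense (cseq) coordinates
.coding_cspan <- function(cmap, L) {
  s <- cmap$segments[cmap$segments$kind == "coding", , drop = FALSE]
  if (nrow(s) != 1L) stop("consequence classification expects one coding segment")
  if (cmap$orientation == "opposite")
    c(L - s$amp_end + 1L, L - s$amp_start + 1L, s$c_anchor)
  else c(s$amp_start, s$amp_end, s$c_anchor)
}

#' Classify the coding consequence of a variant
#'
#' Coding indels with net length change not divisible by 3 are frameshifts;
#' the p. notation is computed by translating the edited coding sequence
#' from the first affected codon to the first stop. SNVs creating a stop are
#' nonsense; other coding SNVs are missense or silent by translation; net
#' mod-3 indels are in-frame. Variants outside the coding segment are
#' noncoding; variants straddling its boundary are conservatively labelled
#' frameshift with a warning flag.
#'
#' @param v a `variant` in amplicon plus-strand coordinates.
#' @param cmap a `coordinate_map`.
#' @param ref_seq amplicon plus-strand sequence.
#' @return a `consequence_call`: list(class, p_notation, boundary_warning).
#' @export
classify_consequence <- function(v, cmap, ref_seq) {
  L <- nchar(ref_seq)
  tr <- .to_coding_space(ref_seq, v, cmap$orientation)
  cseq <- tr$seq; cv <- tr$v
  cs <- .coding_cspan(cmap, L)
  cod_s <- cs[1]; cod_e <- cs[2]; anchor <- cs[3]
  res <- function(class, p = NA_character_, warn = FALSE)
    structure(list(class = class, p_notation = p, boundary_warning = warn),
              class = "consequence_call")
  # interval occupied on cseq; a pure insertion affects the junction (p, p+1)
  lo <- if (cv$kind == "ins") cv$start - 1L else cv$start
  hi <- if (cv$kind == "ins") cv$start else cv$end
  inside <- lo >= cod_s & hi <= cod_e
  overlaps <- hi >= cod_s & lo <= cod_e
  if (!overlaps) return(res("noncoding"))
  if (!inside) {
    if (cv$kind == "SNV") return(res("noncoding"))
    return(res("frameshift", warn = TRUE))
  }
  cnum <- function(q) anchor + (q - cod_s)    # c. number of cseq position
  if (cv$kind == "SNV") {
    cpos <- cnum(cv$start)
    codon_i <- (cpos - 1L) %/% 3L + 1L
    cstart <- cv$start - ((cpos - 1L) %% 3L)
    if (cstart < 1L || cstart + 2L > nchar(cseq)) return(res("noncoding", warn = TRUE))
    old <- substr(cseq, cstart, cstart + 2L)
    new <- old
    substr(new, cv$start - cstart + 1L, cv$start - cstart + 1L) <- cv$alt_allele
    aa_old <- .translate(old); aa_new <- .translate(new)
    if (aa_new == "*")
      return(res("nonsense", paste0("p.", .AA3[aa_old], codon_i, "Ter")))
    if (aa_new == aa_old) return(res("silent", "p.="))
    res("missense", paste0("p.", .AA3[aa_old], codon_i, .AA3[aa_new]))
  } else {
    net <- nchar(cv$alt_allele) - nchar(cv$ref_allele)
    if (net %% 3L == 0L) return(res("inframe_indel"))
    # first potentially affected codon: first transcript position the edit touches
    d <- if (cv$kind == "ins") cnum(cv$start - 1L) + 1L else cnum(cv$start)
    N0 <- (d - 1L) %/% 3L + 1L
    q0 <- cv$start - ((d - 1L) %% 3L)          # cseq position of codon N0 start
    if (q0 < 1L) return(res("frameshift", warn = TRUE))
    edited <- apply_variant_set(cseq, variant_set(cv))
    ref_pep <- .translate(substr(cseq, q0, nchar(cseq)))
    new_pep <- .translate(substr(edited, q0, nchar(edited)))
    m <- min(length(ref_pep), length(new_pep))
    jj <- which(ref_pep[seq_len(m)] != new_pep[seq_len(m)])
    j <- if (length(jj)) jj[1L] else m + 1L
    if (j > length(new_pep)) return(res("frameshift", "p.?"))
    aa_ref <- if (j <= length(ref_pep)) ref_pep[j] else "X"
    aa_new <- new_pep[j]
    pos <- N0 + j - 1L
    if (aa_new == "*")
      return(res("frameshift", paste0("p.", .AA3[aa_ref], pos, "Ter")))
    ter <- which(new_pep[j:length(new_pep)] == "*")
    fs <- if (length(ter)) paste0("fsTer", ter[1L]) else "fsTer?"
    res("frameshift", paste0("p.", .AA3[aa_ref], pos, .AA3[aa_new], fs))
  }
}

# ---- finalization and rendering --------------------------------------------

.vcf_fields <- function(v, ref, ref_seq) {
  vl <- normalize_variant(ref_seq, v, "left")
  if (vl$kind == "SNV" || vl$kind == "delins") {
    list(chrom = ref$chrom, pos = ref$start + vl$start - 1L,
         ref = vl$ref_allele, alt = vl$alt_allele)
  } else if (vl$kind == "del") {
    if (vl$start <= 1L) stop("deletion at position 1 cannot be anchored")
    a <- .substr1(ref_seq, vl$start - 1L)
    list(chrom = ref$chrom, pos = ref$start + vl$start - 2L,
         ref = paste0(a, vl$ref_allele), alt = a)
  } else { # ins / dup
    p <- vl$start - 1L
    if (p < 1L) stop("insertion before position 1 cannot be anchored")
    a <- .substr1(ref_seq, p)
    list(chrom = ref$chrom, pos = ref$start + p - 1L,
         ref = a, alt = paste0(a, vl$alt_allele))
  }
}

#' Finalize raw calls: normalization, HGVS and VCF renderings, consequences
#'
#' Each indel is 3'-shifted on the transcript sense and duplication-classified
#' for HGVS, and left-aligned with an anchor base for VCF; both renderings
#' are sequence-equivalent to the stored variant. Consequence classes are
#' attached. Applying the finalized set to the reference reproduces the
#' de-gapped query over the aligned region (checked by the pipeline driver).
#'
#' @param calls list of raw `variant` objects.
#' @param ref an `amplicon_reference`.
#' @param cmap a `coordinate_map`.
#' @param zygosity zygosity assigned to all calls (pipeline rule: one contig
#'   in a male is hemizygous, in a female unknown).
#' @param caller caller label stored on each call.
#' @param support support value (contig id or depth) stored on each call.
#' @return list of `variant_call` objects.
#' @export
finalize_calls <- function(calls, ref, cmap,
                           zygosity = "unknown", caller = "assembly",
                           support = NA) {
  lapply(calls, function(v) {
    v$zygosity <- zygosity
    hg <- to_hgvs_c(v, cmap, ref$plus_seq)
    vf <- .vcf_fields(v, ref, ref$plus_seq)
    cons <- classify_consequence(v, cmap, ref$plus_seq)
    structure(list(variant = v, caller = caller, zygosity = zygosity,
                   support = support, hgvs_c = hg, consequence = cons$class,
                   p_notation = cons$p_notation,
                   boundary_warning = cons$boundary_warning,
                   vcf = vf, frequency = NA_real_, rsid = NA_character_,
                   flags = character(0)),
              class = "variant_call")
  })
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("%s  %s  %s:%d %s>%s  [%s, %s]%s\n", x$hgvs_c,
              ifelse(is.na(x$p_notation), "", x$p_notation),
              x$vcf$chrom, x$vcf$pos, x$vcf$ref, x$vcf$alt,
              x$consequence, x$zygosity,
              if (length(x$flags)) paste0(" {", paste(x$flags, collapse = ","), "}") else ""))
  invisible(x)
}

#' Tabulate a list of variant calls
#'
#' @param calls list of `variant_call` objects.
#' @return data.frame with one row per call.
#' @export
calls_table <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(hgvs_c = character(0), p_notation = character(0),
                      consequence = character(0), zygosity = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      frequency = numeric(0), rsid = character(0),
                      flags = character(0), stringsAsFactors = FALSE))
  data.frame(
    hgvs_c = vapply(calls, `[[`, character(1), "hgvs_c"),
    p_notation = vapply(calls, `[[`, character(1), "p_notation"),
    consequence = vapply(calls, `[[`, character(1), "consequence"),
    zygosity = vapply(calls, `[[`, character(1), "zygosity"),
    chrom = vapply(calls, function(x) x$vcf$chrom, character(1)),
    pos = vapply(calls, function(x) as.integer(x$vcf$pos), integer(1)),
    ref = vapply(calls, function(x) x$vcf$ref, character(1)),
    alt = vapply(calls, function(x) x$vcf$alt, character(1)),
    frequency = vapply(calls, `[[`, numeric(1), "frequency"),
    rsid = vapply(calls, `[[`, character(1), "rsid"),
    flags = vapply(calls, function(x) paste(x$flags, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Keep only nonsense and frameshift calls
#'
#' The mutational spectrum at this locus is dominated by frameshift and
#' nonsense alleles, so only those classes are prioritized; the full call
#' list stays in the report.
#'
#' @param calls list of `variant_call` objects.
#' @return the prioritized subset.
#' @export
prioritize <- function(calls) {
  calls[vapply(calls, function(x) x$consequence %in% c("frameshift", "nonsense"),
               logical(1))]
}

#' Read a population-frequency table
#'
#' TSV with columns chrom, pos, ref, alt, freq_percent, rsid (left-aligned,
#' anchored representation). Malformed rows are skipped with a warning.
#'
#' @param path TSV path.
#' @return data.frame of frequency records.
#' @export
read_frequency_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "freq_percent")
  if (!all(need %in% names(df))) stop("frequency table must have columns ",
                                      paste(need, collapse = ", "))
  if (!"rsid" %in% names(df)) df$rsid <- NA_character_
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt) |
    is.na(suppressWarnings(as.numeric(df$freq_percent))) |
    suppressWarnings(as.numeric(df$freq_percent)) < 0 |
    suppressWarnings(as.numeric(df$freq_percent)) > 100
  if (any(bad)) {
    warning(sum(bad), " malformed frequency rows skipped")
    df <- df[!bad, , drop = FALSE]
  }
  df$pos <- as.integer(df$pos)
  df$freq_percent <- as.numeric(df$freq_percent)
  df
}

#' Annotate calls with population frequencies
#'
#' Matching is exact on the left-aligned anchored VCF key
#' (chrom:pos:ref:alt); misses keep an explicit NA marker. 3'-shifted HGVS
#' coordinates are never used as keys — in repeat tracts the two
#' normalizations name different positions for the same edit.
#'
#' @param calls list of `variant_call` objects.
#' @param table data.frame from [read_frequency_table()].
#' @return the annotated calls.
#' @export
annotate_frequency <- function(calls, table) {
  key <- function(ch, p, r, a) paste(ch, p, r, a, sep = ":")
  tk <- key(table$chrom, table$pos, table$ref, table$alt)
  lapply(calls, function(x) {
    i <- match(key(x$vcf$chrom, x$vcf$pos, x$vcf$ref, x$vcf$alt), tk)
    if (!is.na(i)) {
      x$frequency <- table$freq_percent[i]
      x$rsid <- if (is.na(table$rsid[i])) NA_character_ else table$rsid[i]
    }
    x
  })
}

# ---- VCF output -------------------------------------------------------------

.GT <- c(hemizygous = "1", homozygous = "1/1", heterozygous = "0/1",
         unknown = "./.")

#' Write calls as VCF 4.2
#'
#' Indels are anchored with the preceding base and left-aligned; records are
#' sorted by position. GT is 1 for hemizygous, 1/1 for homozygous, 0/1 for
#' heterozygous calls.
#'
#' @param calls list of `variant_call` objects.
#' @param ref an `amplicon_reference` (locus for CHROM/POS and contig header).
#' @param path output path, or NULL to return the text invisibly only.
#' @param sample_id sample column name.
#' @return the VCF lines, invisibly.
#' @export
write_vcf <- function(calls, ref, path = NULL, sample_id = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", ref$chrom, ref$end),
           sprintf("##reference=%s", ref$name),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  if (length(calls)) {
    pos <- vapply(calls, function(x) as.integer(x$vcf$pos), integer(1))
    calls <- calls[order(pos)]
    recs <- vapply(calls, function(x) {
      gt <- .GT[[x$zygosity]]
      id <- if (!is.na(x$rsid) && nzchar(x$rsid)) x$rsid else "."
      info <- if (!is.na(x$frequency)) sprintf("AF_PCT=%g", x$frequency) else "."
      paste(x$vcf$chrom, x$vcf$pos, id, x$vcf$ref, x$vcf$alt, ".", "PASS",
            info, "GT", gt, sep = "\t")
    }, character(1))
  } else recs <- character(0)
  lines <- c(hdr, recs)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse a VCF written by [write_vcf()] back into variants
#'
#' Undoes the anchor base and returns interval-replacement variants in
#' amplicon plus-strand coordinates with zygosity from GT.
#'
#' @param path VCF path (or character vector of lines).
#' @param ref the `amplicon_reference` the file was written against.
#' @return list of `variant` objects.
#' @export
parse_vcf <- function(path, ref) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  rec <- lines[!startsWith(lines, "#")]
  lapply(rec, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[2]) - ref$start + 1L
    refa <- f[4]; alta <- f[5]
    zyg <- names(.GT)[match(f[10], .GT)]
    if (is.na(zyg)) zyg <- "unknown"
    if (nchar(refa) > 1L || nchar(alta) > 1L) {
      # anchored indel: strip shared leading base
      if (substr(refa, 1L, 1L) == substr(alta, 1L, 1L)) {
        refa <- substr(refa, 2L, nchar(refa))
        alta <- substr(alta, 2L, nchar(alta))
        pos <- pos + 1L
      }
    }
    if (nchar(refa) == 0L) variant(pos, pos - 1L, "", alta, zyg)
    else variant(pos, pos + nchar(refa) - 1L, refa, alta, zyg)
  })
}
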