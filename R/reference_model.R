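# Reference, coordinate and variant data model.
#
# Variants are stored as interval replacements on the amplicon plus strand:
# the reference bases over [start, end] are replaced by alt. A pure insertion
# after position p is encoded as start = p + 1, end = p with an empty ref
# allele. No VCF-style anchor base is stored; anchoring happens only at VCF
# export. This keeps the sequence-equivalence algebra trivial.

#' Amplicon reference
#'
#' Container for the plus-strand sequence of a single PCR amplicon, its
#' genomic locus, primer spans and coding-strand orientation. For the ORF15
#' model system the coding strand is the minus strand: the plus strand is
#' G-poor (the property used to orient and filter contigs) while the coding
#' strand is purine-rich.
#'
#' @param name reference name (FASTA record id).
#' @param plus_seq plus-strand sequence, uppercase ACGT.
#' @param chrom chromosome label of the locus.
#' @param start,end 1-based inclusive genomic coordinates of the amplicon.
#' @param primer_fwd,primer_rev integer length-2 vectors, primer intervals in
#'   amplicon coordinates.
#' @param coding_strand `"plus"` or `"minus"`.
#' @return an `amplicon_reference` object.
#' @export
amplicon_reference <- function(name, plus_seq, chrom, start, end,
                               primer_fwd, primer_rev,
                               coding_strand = c("minus", "plus")) {
  coding_strand <- match.arg(coding_strand)
  .check_dna(plus_seq, "plus_seq")
  L <- nchar(plus_seq)
  if (end - start + 1L != L)
    stop("locus span (", end - start + 1L, ") does not match sequence length (", L, ")")
  for (pr in list(primer_fwd, primer_rev)) {
    if (length(pr) != 2L || any(pr < 1L) || any(pr > L) || pr[1] > pr[2])
      stop("primer interval outside [1, ", L, "]")
  }
  structure(list(name = name, plus_seq = plus_seq, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 primer_fwd = as.integer(primer_fwd),
                 primer_rev = as.integer(primer_rev),
                 coding_strand = coding_strand),
            class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("Amplicon reference '", x$name, "': ", x$chrom, ":", x$start, "-", x$end,
      " (", nchar(x$plus_seq), " bp, coding strand ", x$coding_strand,
      ", plus-strand G ", sprintf("%.2f%%", 100 * g_fraction(x$plus_seq)),
      ")\n", sep = "")
  invisible(x)
}

#' Length of an amplicon locus from its printed coordinates
#'
#' @param ref an `amplicon_reference`, or NULL if `start`/`end` given.
#' @param start,end 1-based inclusive genomic coordinates.
#' @return interval length in bp.
#' @export
locus_length <- function(ref = NULL, start = NULL, end = NULL) {
  if (!is.null(ref)) { start <- ref$start; end <- ref$end }
  as.integer(end) - as.integer(start) + 1L
}

#' Write / read an amplicon reference as FASTA plus a YAML locus config
#'
#' The FASTA holds the single plus-strand record; the YAML records the
#' genomic locus, primer spans, coding-strand orientation, and the
#' transcript coordinate-map segments.
#'
#' @param ref an `amplicon_reference`.
#' @param cmap a `coordinate_map` (or NULL to omit).
#' @param fasta_path,config_path output (input) paths.
#' @return `write_reference` returns the paths invisibly; `read_reference`
#'   a list with `ref` and `cmap`.
#' @export
write_reference <- function(ref, cmap, fasta_path, config_path) {
  writeLines(c(paste0(">", ref$name), ref$plus_seq), fasta_path)
  cfg <- list(name = ref$name, chrom = ref$chrom, start = ref$start,
              end = ref$end, primer_fwd = ref$primer_fwd,
              primer_rev = ref$primer_rev, coding_strand = ref$coding_strand)
  if (!is.null(cmap)) {
    cfg$transcript_id <- cmap$transcript_id
    cfg$orientation <- cmap$orientation
    cfg$segments <- lapply(seq_len(nrow(cmap$segments)), function(i)
      as.list(cmap$segments[i, ]))
  }
  yaml::write_yaml(cfg, config_path)
  invisible(c(fasta = fasta_path, config = config_path))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta_path, config_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  if (length(x) != 1L) stop("reference FASTA must hold a single record")
  cfg <- yaml::read_yaml(config_path)
  ref <- amplicon_reference(name = cfg$name, plus_seq = as.character(x[[1]]),
                            chrom = cfg$chrom, start = cfg$start, end = cfg$end,
                            primer_fwd = unlist(cfg$primer_fwd),
                            primer_rev = unlist(cfg$primer_rev),
                            coding_strand = cfg$coding_strand)
  cmap <- NULL
  if (!is.null(cfg$segments)) {
    segs <- do.call(rbind, lapply(cfg$segments, function(s)
      data.frame(amp_start = s$amp_start, amp_end = s$amp_end, kind = s$kind,
                 c_anchor = s$c_anchor, stringsAsFactors = FALSE)))
    cmap <- coordinate_map(cfg$transcript_id, cfg$orientation, segs)
  }
  list(ref = ref, cmap = cmap)
}

#' Transcript coordinate map
#'
#' Maps amplicon plus-strand positions to HGVS c. labels. Segments are
#' non-overlapping amplicon intervals of kind `coding`, `intron_offset`
#' (emits `c.<anchor>-K`) or `utr3` (emits `c.*N`). `c_anchor` is the
#' transcript coordinate at the transcript-5' edge of the segment (for
#' `intron_offset` it is the anchor coding position the offsets hang off).
#'
#' @param transcript_id transcript label used for reporting.
#' @param orientation `"same"` or `"opposite"`: transcript sense relative to
#'   the amplicon plus strand.
#' @param segments data.frame with columns `amp_start`, `amp_end`, `kind`,
#'   `c_anchor`.
#' @return a `coordinate_map` object.
#' @export
coordinate_map <- function(transcript_id, orientation = c("opposite", "same"),
                           segments) {
  orientation <- match.arg(orientation)
  need <- c("amp_start", "amp_end", "kind", "c_anchor")
  if (!all(need %in% names(segments))) stop("segments must have columns ", paste(need, collapse = ", "))
  if (!all(segments$kind %in% c("coding", "intron_offset", "utr3")))
    stop("unknown segment kind")
  segments <- segments[order(segments$amp_start), , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments$amp_start[-1L] <= segments$amp_end[-nrow(segments)]))
    stop("segments overlap")
  structure(list(transcript_id = transcript_id, orientation = orientation,
                 segments = segments),
            class = "coordinate_map")
}

#' Construct a variant (interval replacement on the amplicon plus strand)
#'
#' @param start,end 1-based amplicon interval; `end == start - 1` encodes a
#'   pure insertion after `start - 1`.
#' @param ref_allele reference bases over the interval (empty for insertion).
#' @param alt_allele replacement bases (empty for deletion).
#' @param zygosity one of hemizygous, homozygous, heterozygous, unknown.
#' @return a `variant` object with derived `kind` (SNV/del/ins/delins; `dup`
#'   is assigned by [classify_dup()]).
#' @export
variant <- function(start, end, ref_allele, alt_allele,
                    zygosity = c("unknown", "hemizygous", "homozygous", "heterozygous")) {
  zygosity <- match.arg(zygosity)
  start <- as.integer(start); end <- as.integer(end)
  if (end < start - 1L) stop("end must be >= start - 1")
  if (nchar(ref_allele) != end - start + 1L)
    stop("ref_allele length does not match interval [", start, ",", end, "]")
  if (nchar(ref_allele) > 0 && grepl("[^ACGT]", ref_allele)) stop("ref_allele not ACGT")
  if (nchar(alt_allele) > 0 && grepl("[^ACGT]", alt_allele)) stop("alt_allele not ACGT")
  if (identical(ref_allele, alt_allele)) stop("ref and alt alleles are identical")
  kind <- if (nchar(ref_allele) == 0L) "ins"
  else if (nchar(alt_allele) == 0L) "del"
  else if (nchar(ref_allele) == 1L && nchar(alt_allele) == 1L) "SNV"
  else "delins"
  structure(list(start = start, end = end, ref_allele = ref_allele,
                 alt_allele = alt_allele, kind = kind, zygosity = zygosity),
            class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant %s %d-%d %s>%s [%s, %s]\n", x$kind, x$start, x$end,
              ifelse(nchar(x$ref_allele), x$ref_allele, "-"),
              ifelse(nchar(x$alt_allele), x$alt_allele, "-"),
              x$zygosity,
              if (!is.null(attr(x, "dup_start")))
                paste0("dup of ", attr(x, "dup_start"), "-", attr(x, "dup_end"))
              else "raw"))
  invisible(x)
}

#' Construct a variant set
#'
#' A set of pairwise non-overlapping variants, sorted by start so application
#' order is irrelevant.
#'
#' @param ... `variant` objects, or a single list of them.
#' @return a `variant_set`.
#' @export
variant_set <- function(...) {
  vs <- list(...)
  if (length(vs) == 1L && is.list(vs[[1]]) && !inherits(vs[[1]], "variant"))
    vs <- vs[[1]]
  if (!all(vapply(vs, inherits, logical(1), "variant")))
    stop("all elements must be variant objects")
  if (length(vs)) {
    vs <- vs[order(vapply(vs, `[[`, integer(1), "start"),
                   vapply(vs, `[[`, integer(1), "end"))]
    starts <- vapply(vs, `[[`, integer(1), "start")
    ends <- vapply(vs, `[[`, integer(1), "end")
    if (length(vs) > 1L && any(starts[-1L] <= ends[-length(ends)]))
      stop("variants overlap; overlapping sets are rejected, not merged")
    if (anyDuplicated(starts[ends < starts]))
      stop("two insertions at the same position are ambiguous")
  }
  structure(vs, class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set of", length(x), "variants>\n")
  for (v in x) print(v)
  invisible(x)
}

.validate_against_ref <- function(ref_seq, vs) {
  L <- nchar(ref_seq)
  for (v in vs) {
    if (v$start < 1L || v$end > L)
      stop("variant at ", v$start, "-", v$end, " outside reference [1,", L, "]")
    if (v$end >= v$start) {
      obs <- substr(ref_seq, v$start, v$end)
      if (obs != v$ref_allele)
        stop("ref-allele mismatch at ", v$start, "-", v$end,
             ": expected '", v$ref_allele, "', reference has '", obs, "'")
    }
  }
  invisible(TRUE)
}

#' Apply a variant set to a reference sequence
#'
#' Each interval `[start, end]` is replaced by its alt allele, applied
#' right-to-left so earlier coordinates stay valid.
#'
#' @param ref_seq reference plus-strand sequence.
#' @param vs a `variant_set` (or list of variants).
#' @return the edited sequence.
#' @export
apply_variant_set <- function(ref_seq, vs) {
  .check_dna(ref_seq, "ref_seq")
  if (!inherits(vs, "variant_set")) vs <- variant_set(vs)
  .validate_against_ref(ref_seq, vs)
  out <- ref_seq
  for (v in rev(vs)) {
    out <- paste0(substr(out, 1L, v$start - 1L), v$alt_allele,
                  substr(out, v$end + 1L, nchar(out)))
  }
  out
}

#' Sequence equivalence of two variant sets
#'
#' Two call sets are equivalent when applying each to the reference yields
#' the identical sequence — the relation underlying "two different ways to
#' call the same allele" in repeat tracts.
#'
#' @inheritParams apply_variant_set
#' @param a,b `variant_set` objects.
#' @return TRUE/FALSE.
#' @export
sets_equivalent <- function(ref_seq, a, b) {
  identical(apply_variant_set(ref_seq, a), apply_variant_set(ref_seq, b))
}

#' Shift an indel to its most-3' (or most-5') equivalent representation
#'
#' Pure insertions and deletions inside repeat tracts have several
#' sequence-identical representations; HGVS requires the most-3' one on the
#' transcript sense, VCF the left-aligned one on the genomic plus strand.
#' The shift never changes the edited product and is idempotent. SNVs and
#' delins variants are returned unchanged.
#'
#' @param ref_seq sequence the variant is expressed against.
#' @param v a `variant`.
#' @param direction `"right"` (3' on this strand) or `"left"`.
#' @return the shifted `variant`.
#' @export
normalize_variant <- function(ref_seq, v, direction = c("right", "left")) {
  direction <- match.arg(direction)
  if (!v$kind %in% c("ins", "del", "dup")) return(v)
  L <- nchar(ref_seq)
  if (v$kind == "del") {
    s <- v$start; e <- v$end
    if (direction == "right") {
      while (e + 1L <= L && .substr1(ref_seq, e + 1L) == .substr1(ref_seq, s)) {
        s <- s + 1L; e <- e + 1L
      }
    } else {
      while (s - 1L >= 1L && .substr1(ref_seq, e) == .substr1(ref_seq, s - 1L)) {
        s <- s - 1L; e <- e - 1L
      }
    }
    variant(s, e, substr(ref_seq, s, e), "", v$zygosity)
  } else { # ins (or dup treated as its ins form)
    p <- v$start - 1L          # insert after p
    ins <- v$alt_allele
    n <- nchar(ins)
    if (direction == "right") {
      while (p + 1L <= L && .substr1(ref_seq, p + 1L) == .substr1(ins, 1L)) {
        ins <- paste0(substr(ins, 2L, n), .substr1(ref_seq, p + 1L))
        p <- p + 1L
      }
    } else {
      while (p >= 1L && .substr1(ref_seq, p) == .substr1(ins, n)) {
        ins <- paste0(.substr1(ref_seq, p), substr(ins, 1L, n - 1L))
        p <- p - 1L
      }
    }
    variant(p + 1L, p, "", ins, v$zygosity)
  }
}

#' @rdname normalize_variant
#' @export
normalize_3prime <- function(ref_seq, v) normalize_variant(ref_seq, v, "right")

#' Re-express an insertion as a duplication when possible
#'
#' If the inserted string equals the reference segment of the same length
#' immediately 5' of the insertion point, the insertion is a tandem
#' duplication of that segment. Insertions longer than the available 5'
#' context are never classified dup. The interval-replacement content is
#' unchanged; only `kind` and the `dup_start`/`dup_end` attributes are set.
#'
#' @param ref_seq sequence the variant is expressed against (same strand
#'   sense the dup should be named on).
#' @param v a 3'-normalized insertion `variant`; others returned unchanged.
#' @return the (possibly re-classified) `variant`.
#' @export
classify_dup <- function(ref_seq, v) {
  if (v$kind != "ins") return(v)
  p <- v$start - 1L
  n <- nchar(v$alt_allele)
  if (p >= n && substr(ref_seq, p - n + 1L, p) == v$alt_allele) {
    v$kind <- "dup"
    attr(v, "dup_start") <- p - n + 1L
    attr(v, "dup_end") <- p
  }
  v
}

# ---- coordinate-space transforms -------------------------------------------

# variant expressed on the amplicon plus strand -> coding-sense space
.to_coding_space <- function(ref_seq, v, orientation) {
  if (orientation == "same") return(list(seq = ref_seq, v = v))
  L <- nchar(ref_seq)
  cs <- L - v$end + 1L
  ce <- L - v$start + 1L
  nv <- variant(cs, ce,
                if (nchar(v$ref_allele)) cpp_revcomp(v$ref_allele) else "",
                if (nchar(v$alt_allele)) cpp_revcomp(v$alt_allele) else "",
                v$zygosity)
  list(seq = cpp_revcomp(ref_seq), v = nv)
}

# inverse transform (the mapping is an involution)
.from_coding_space <- function(cseq, cv, orientation) {
  if (orientation == "same") return(cv)
  L <- nchar(cseq)
  variant(L - cv$end + 1L, L - cv$start + 1L,
          if (nchar(cv$ref_allele)) cpp_revcomp(cv$ref_allele) else "",
          if (nchar(cv$alt_allele)) cpp_revcomp(cv$alt_allele) else "",
          cv$zygosity)
}

# amplicon plus-strand position -> c. label pieces
.amp_pos_to_label <- function(pos, cmap) {
  seg <- cmap$segments
  hit <- which(pos >= seg$amp_start & pos <= seg$amp_end)
  if (length(hit) != 1L)
    stop("position ", pos, " is not covered by the coordinate map (unmappable)")
  s <- seg[hit, ]
  off5 <- if (cmap$orientation == "opposite") s$amp_end - pos else pos - s$amp_start
  seg_len <- s$amp_end - s$amp_start + 1L
  switch(s$kind,
         coding = as.character(s$c_anchor + off5),
         intron_offset = paste0(s$c_anchor, "-", seg_len - off5),
         utr3 = paste0("*", s$c_anchor + off5))
}

# c. label -> amplicon plus-strand position
.label_to_amp_pos <- function(label, cmap) {
  seg <- cmap$segments
  opp <- cmap$orientation == "opposite"
  if (grepl("^\\*", label)) {
    n <- as.integer(sub("^\\*", "", label))
    s <- seg[seg$kind == "utr3", , drop = FALSE]
    if (nrow(s) != 1L) stop("no utr3 segment in map")
    off5 <- n - s$c_anchor
  } else if (grepl("-", label, fixed = TRUE)) {
    parts <- strsplit(label, "-", fixed = TRUE)[[1]]
    anchor <- as.integer(parts[1]); k <- as.integer(parts[2])
    s <- seg[seg$kind == "intron_offset" & seg$c_anchor == anchor, , drop = FALSE]
    if (nrow(s) != 1L) stop("no intron segment anchored at ", anchor)
    off5 <- (s$amp_end - s$amp_start + 1L) - k
  } else {
    n <- as.integer(label)
    s <- seg[seg$kind == "coding", , drop = FALSE]
    s <- s[n >= s$c_anchor & n <= s$c_anchor + (s$amp_end - s$amp_start), , drop = FALSE]
    if (nrow(s) != 1L) stop("coding position ", n, " outside mapped segments")
    off5 <- n - s$c_anchor
  }
  if (is.na(off5) || off5 < 0L || off5 > s$amp_end - s$amp_start)
    stop("label '", label, "' outside its segment")
  if (opp) s$amp_end - off5 else s$amp_start + off5
}

# amplicon position -> coding-sense (cseq) position and back
.amp_to_cpos <- function(pos, L, orientation) {
  if (orientation == "opposite") L - pos + 1L else pos
}

# ---- HGVS c. emission and parsing ------------------------------------------

#' Emit HGVS c. nomenclature for a variant
#'
#' The variant is transformed to transcript (coding) sense, 3'-shifted there,
#' duplication-classified, and rendered with segment-aware labels: coding
#' positions as `c.N`, intronic ones as `c.<anchor>-K`, 3'UTR ones as `c.*N`.
#' Alleles are reported on the transcript strand.
#'
#' @param v a `variant` in amplicon plus-strand coordinates.
#' @param cmap a `coordinate_map`.
#' @param ref_seq the amplicon plus-strand sequence.
#' @return an HGVS c. string.
#' @export
to_hgvs_c <- function(v, cmap, ref_seq) {
  tr <- .to_coding_space(ref_seq, v, cmap$orientation)
  cseq <- tr$seq
  cv <- classify_dup(cseq, normalize_variant(cseq, tr$v, "right"))
  L <- nchar(cseq)
  # label for a cseq position: map back to amplicon coordinates first
  lab <- function(cpos) {
    amp <- if (cmap$orientation == "opposite") L - cpos + 1L else cpos
    .amp_pos_to_label(amp, cmap)
  }
  if (cv$kind == "SNV") {
    paste0("c.", lab(cv$start), cv$ref_allele, ">", cv$alt_allele)
  } else if (cv$kind == "del") {
    if (cv$start == cv$end)
      paste0("c.", lab(cv$start), "del", cv$ref_allele)
    else
      paste0("c.", lab(cv$start), "_", lab(cv$end), "del")
  } else if (cv$kind == "dup") {
    ds <- attr(cv, "dup_start"); de <- attr(cv, "dup_end")
    if (ds == de) paste0("c.", lab(ds), "dup")
    else paste0("c.", lab(ds), "_", lab(de), "dup")
  } else if (cv$kind == "ins") {
    p <- cv$start - 1L
    if (p < 1L || p + 1L > L) stop("insertion at sequence boundary is unmappable")
    paste0("c.", lab(p), "_", lab(p + 1L), "ins", cv$alt_allele)
  } else { # delins
    if (cv$start == cv$end)
      paste0("c.", lab(cv$start), "delins", cv$alt_allele)
    else
      paste0("c.", lab(cv$start), "_", lab(cv$end), "delins", cv$alt_allele)
  }
}

#' Parse an HGVS c. string of the dialect emitted by [to_hgvs_c()]
#'
#' Inverse of [to_hgvs_c()] up to 3' normalization: parsing an emitted string
#' and applying the result reproduces the original edit.
#'
#' @param text HGVS c. string.
#' @inheritParams to_hgvs_c
#' @return a `variant` in amplicon plus-strand coordinates.
#' @export
parse_hgvs_c <- function(text, cmap, ref_seq) {
  pos_re <- "(\\*?\\d+(?:-\\d+)?)"
  m <- regmatches(text, regexec(
    paste0("^c\\.", pos_re, "(?:_", pos_re, ")?",
           "(?:(delins)([ACGT]+)|(del)([ACGT]*)|(dup)|(ins)([ACGT]+)|([ACGT])>([ACGT]))$"),
    text))[[1]]
  if (length(m) == 0L) stop("cannot parse HGVS string '", text, "'")
  lab1 <- m[2]; lab2 <- m[3]
  op <- c(delins = m[4] != "", del = m[6] != "", dup = m[8] != "",
          ins = m[9] != "", snv = m[11] != "")
  L <- nchar(ref_seq)
  opp <- cmap$orientation == "opposite"
  cpos <- function(lab) {
    amp <- .label_to_amp_pos(lab, cmap)
    if (opp) L - amp + 1L else amp
  }
  cseq <- if (opp) cpp_revcomp(ref_seq) else ref_seq
  p1 <- cpos(lab1)
  p2 <- if (nzchar(lab2)) cpos(lab2) else p1
  cv <- if (op["snv"]) {
    if (substr(cseq, p1, p1) != m[11])
      stop("reference allele mismatch for '", text, "'")
    variant(p1, p1, m[11], m[12])
  } else if (op["del"]) {
    refb <- substr(cseq, p1, p2)
    if (nzchar(m[7]) && refb != m[7])
      stop("deleted bases in '", text, "' do not match the reference")
    variant(p1, p2, refb, "")
  } else if (op["dup"]) {
    variant(p2 + 1L, p2, "", substr(cseq, p1, p2))
  } else if (op["ins"]) {
    if (p2 != p1 + 1L) stop("ins positions must be adjacent in '", text, "'")
    variant(p1 + 1L, p1, "", m[10])
  } else { # delins
    variant(p1, p2, substr(cseq, p1, p2), m[5])
  }
  v <- .from_coding_space(cseq, cv, cmap$orientation)
  .validate_against_ref(ref_seq, list(v))
  v
}
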