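test_that("identical sequences align gap-free at the match-score optimum", {
  s <- rand_dna(100)
  aln <- global_align(s, s)
  expect_identical(aln$score, 100)
  expect_identical(aln$ref_row, s)
  expect_identical(aln$query_row, s)
  expect_length(calls_from_alignment(aln), 0L)
})

test_that("the DP aligner matches the exhaustive enumeration optimum", {
  set.seed(77)
  p <- align_params()
  for (i in 1:120) {
    n <- sample(1:12, 1); m <- sample(1:12, 1)
    a <- rand_dna(n)
    b <- if (runif(1) < 0.5) rand_dna(m) else {
      # correlated pair: mutate a few bases of a
      x <- a
      for (j in sample(n, min(n, 2))) substr(x, j, j) <- sample(c("A", "C", "G", "T"), 1)
      x
    }
    dp <- global_align(a, b, p)$score
    bf <- orf15asm:::cpp_bruteforce_align_score(a, b, p$match, p$mismatch,
                                                p$gap_open, p$gap_extend)
    expect_equal(dp, bf, info = paste(a, b))
  }
})

test_that("a duplication aligns as one contiguous gap run and is called dup", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  truths <- spike_standard_truthsets(ref)
  hap <- apply_variant_set(ref$plus_seq, truths$dup27)
  aln <- global_align(hap, ref$plus_seq)
  gaps <- gregexpr("-+", aln$ref_row)[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length")[1], 27L)
  calls <- calls_from_alignment(aln)
  expect_length(calls, 1L)
  fin <- finalize_calls(calls, ref, cmap, zygosity = "hemizygous")
  expect_match(fin[[1]]$hgvs_c, "^c\\.\\d+_\\d+dup$")
  expect_true(sets_equivalent(ref$plus_seq, variant_set(calls), truths$dup27))
})

test_that("a mismatch adjacent to a gap merges into a single delins event", {
  set.seed(88)
  ref <- rand_dna(100)
  # replace ref[50..52] by a base absent from that window: the edit cannot
  # reduce to a pure deletion, so the aligner must pair a mismatch column
  # with an adjacent gap run
  b <- setdiff(c("A", "C", "G", "T"), strsplit(substr(ref, 50, 52), "")[[1]])[1]
  skip_if(is.na(b), "window uses all four bases")
  q <- paste0(substr(ref, 1, 49), b, substr(ref, 53, 100))
  aln <- global_align(q, ref)
  calls <- calls_from_alignment(aln)
  expect_length(calls, 1L)
  expect_identical(calls[[1]]$kind, "delins")
  expect_identical(apply_variant_set(ref, variant_set(calls)), q)
})

test_that("per-column SNVs come from gap-free mismatch runs", {
  ref <- rand_dna(200)
  q <- ref
  substr(q, 50, 50) <- if (substr(ref, 50, 50) == "A") "C" else "A"
  substr(q, 120, 120) <- if (substr(ref, 120, 120) == "G") "T" else "G"
  calls <- calls_from_alignment(global_align(q, ref))
  expect_length(calls, 2L)
  expect_true(all(vapply(calls, `[[`, character(1), "kind") == "SNV"))
  expect_identical(vapply(calls, `[[`, integer(1), "start"), c(50L, 120L))
})

test_that("finalized VCF is left-shifted while HGVS is 3'-shifted", {
  # deletion of one T from a T3 run: VCF anchors before the run, HGVS names
  # the transcript-3' copy; on an opposite-orientation map the two renderings
  # fall at different reference positions
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  plus <- ref$plus_seq
  tt <- as.integer(regexpr("CTTTC", plus, fixed = TRUE))
  skip_if(tt < 0, "fixture lacks a T3 run")
  s <- tt + 1L
  v <- variant(s + 1L, s + 1L, "T", "")   # delete the middle T
  fin <- finalize_calls(list(v), ref, cmap)[[1]]
  # VCF: left aligned, anchored at the base before the first T
  expect_identical(fin$vcf$pos, ref$start + s - 2L)
  expect_identical(substr(fin$vcf$ref, 1, 1), fin$vcf$alt)
  # HGVS names a position whose plus-strand coordinate is the run's first T
  # (transcript 3' = plus-strand 5' on an opposite-orientation map)
  parsed <- parse_hgvs_c(fin$hgvs_c, cmap, plus)
  expect_identical(parsed$start, s)
  expect_true(sets_equivalent(plus, variant_set(v), variant_set(parsed)))
})

test_that("consequence classes follow frame arithmetic and translation", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  truths <- spike_standard_truthsets(ref)
  cls <- function(nm) classify_consequence(truths[[nm]][[1]], cmap, ref$plus_seq)
  expect_identical(cls("del2")$class, "frameshift")
  expect_identical(cls("del4")$class, "frameshift")
  expect_identical(cls("dup27")$class, "inframe_indel")
  expect_identical(cls("dup15")$class, "inframe_indel")
  expect_identical(cls("ins51")$class, "inframe_indel")
  snv <- cls("snv")
  expect_identical(snv$class, "nonsense")
  expect_match(snv$p_notation, "^p\\.Glu\\d+Ter$")
  fs <- cls("del2")
  expect_match(fs$p_notation, "^p\\.[A-Z][a-z]{2}\\d+([A-Z][a-z]{2}fsTer\\d+|Ter)$")
})

test_that("frameshift classification agrees with direct translation", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  plus <- ref$plus_seq
  st <- attr(ref, "structure")
  cseq <- revcomp(plus)
  L <- nchar(plus)
  set.seed(55)
  for (i in 1:50) {
    # random coding indel, safely inside the coding segment
    q <- sample((st$coding[1] + 30L):(st$coding[2] - 60L), 1)
    amp <- L - q + 1L
    w <- sample(1:9, 1)
    v <- if (runif(1) < 0.5) variant(amp - w + 1L, amp,
                                     substr(plus, amp - w + 1L, amp), "")
    else variant(amp + 1L, amp, "", rand_dna(w))
    got <- classify_consequence(v, cmap, plus)$class
    net <- nchar(v$alt_allele) - nchar(v$ref_allele)
    # independent oracle: translate the edited coding-sense sequence with
    # Biostrings and compare peptide tails
    edited_cseq <- revcomp(apply_variant_set(plus, variant_set(v)))
    # translating a window past the edit suffices to expose a shifted tail
    win_end <- min(q + 300L, st$coding[2])
    cds <- substr(cseq, st$coding[1], win_end)
    cds_ed <- substr(edited_cseq, st$coding[1], win_end)
    trim <- function(x) substr(x, 1L, 3L * (nchar(x) %/% 3L))
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(trim(cds))))
    pep_ed <- as.character(Biostrings::translate(Biostrings::DNAString(trim(cds_ed))))
    shifted <- net %% 3L != 0L
    expect_identical(got == "frameshift", shifted, info = i)
    if (!shifted) expect_identical(got, "inframe_indel", info = i)
    if (shifted) expect_false(identical(pep, pep_ed), info = i)
  }
})

test_that("prioritization keeps exactly the nonsense and frameshift classes", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  truths <- spike_standard_truthsets(ref)
  calls <- finalize_calls(lapply(truths[c("snv", "del2", "dup27", "delins2")],
                                 `[[`, 1L),
                          ref, cmap, zygosity = "hemizygous")
  prio <- prioritize(calls)
  expect_identical(sort(unname(vapply(prio, `[[`, character(1), "consequence"))),
                   c("frameshift", "nonsense"))
  expect_length(prioritize(list()), 0L)
})

test_that("frequency annotation matches only on the left-aligned VCF key", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  plus <- ref$plus_seq
  tt <- as.integer(regexpr("CTTTC", plus, fixed = TRUE))
  s <- tt + 1L
  v <- variant(s + 1L, s + 1L, "T", "")
  fin <- finalize_calls(list(v), ref, cmap)
  good <- data.frame(chrom = fin[[1]]$vcf$chrom, pos = fin[[1]]$vcf$pos,
                     ref = fin[[1]]$vcf$ref, alt = fin[[1]]$vcf$alt,
                     freq_percent = 12.5, rsid = "rs0000001",
                     stringsAsFactors = FALSE)
  ann <- annotate_frequency(fin, good)
  expect_identical(ann[[1]]$frequency, 12.5)
  expect_identical(ann[[1]]$rsid, "rs0000001")
  # a record keyed at the 3'-shifted HGVS position must NOT match
  parsed <- parse_hgvs_c(fin[[1]]$hgvs_c, cmap, plus)
  wrong <- good
  wrong$pos <- ref$start + parsed$start - 1L
  expect_false(identical(wrong$pos, good$pos))
  ann2 <- annotate_frequency(finalize_calls(list(v), ref, cmap), wrong)
  expect_true(is.na(ann2[[1]]$frequency))
  # malformed rows are skipped with a warning
  tf <- tempfile(fileext = ".tsv")
  bad <- rbind(good, data.frame(chrom = "chrX", pos = 5, ref = "NN", alt = "A",
                                freq_percent = 1, rsid = NA))
  write.table(bad, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(tab <- read_frequency_table(tf), "malformed")
  expect_identical(nrow(tab), 1L)
  unlink(tf)
})

test_that("VCF writing anchors indels and round-trips through the parser", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  truths <- spike_standard_truthsets(ref)
  vs <- lapply(truths[c("snv", "del2", "dup27", "ins51")], `[[`, 1L)
  fin <- finalize_calls(vs, ref, cmap, zygosity = "hemizygous")
  tf <- tempfile(fileext = ".vcf")
  lines <- write_vcf(fin, ref, tf, sample_id = "S1")
  recs <- lines[!startsWith(lines, "#")]
  expect_length(recs, 4L)
  pos <- as.integer(vapply(strsplit(recs, "\t"), `[[`, character(1), 2))
  expect_false(is.unsorted(pos))
  # SNV position is plain coordinate arithmetic
  snv_v <- vs$snv
  expect_true((ref$start + snv_v$start - 1L) %in% pos)
  # hemizygous GT is "1"
  expect_true(all(grepl("\t1$", recs)))
  back <- parse_vcf(tf, ref)
  expect_length(back, 4L)
  for (v in vs) {
    hit <- any(vapply(back, function(b)
      sets_equivalent(ref$plus_seq, variant_set(v), variant_set(b)), logical(1)))
    expect_true(hit)
  }
  unlink(tf)
})
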