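test_that("apply_variant_set performs interval replacement right-to-left", {
  expect_identical(apply_variant_set("ACGT", variant_set()), "ACGT")
  expect_identical(
    apply_variant_set("ACGT", variant_set(variant(2, 2, "C", "T"))), "ATGT")
  # duplication of a 6-mer as an insertion after its copy
  vs <- variant_set(variant(7, 6, "", "AAGGAG"))
  expect_identical(apply_variant_set("AAGGAGAAGGAG", vs), "AAGGAGAAGGAGAAGGAG")
  # several variants at once: coordinates never shift
  vs2 <- variant_set(variant(1, 1, "A", "C"),
                     variant(3, 4, "GT", ""),
                     variant(5, 4, "", "TTT"))
  expect_identical(apply_variant_set("ACGTAC", vs2), "CCTTTAC")
})

test_that("invalid variant sets are rejected with position context", {
  expect_error(apply_variant_set("ACGT", variant_set(variant(2, 2, "G", "T"))),
               "mismatch at 2")
  expect_error(variant_set(variant(1, 3, "ACG", ""), variant(2, 2, "C", "A")),
               "overlap")
  expect_error(variant(2, 2, "C", "C"), "identical")
  expect_error(variant_set(variant(3, 2, "", "A"), variant(3, 2, "", "G")),
               "ambiguous")
})

test_that("sets_equivalent compares edited products exactly", {
  r <- "ACGT"
  a <- variant_set(variant(2, 2, "C", "T"))
  expect_true(sets_equivalent(r, a, a))
  b <- variant_set(variant(3, 3, "G", "A"))
  expect_false(sets_equivalent(r, a, b))
})

test_that("distinct representations of one repeat-tract allele are equivalent", {
  # analog of the published case where one allele was called either as a
  # single long insertion or as two tandem duplications
  set.seed(42)
  u <- rand_dna(27)
  u2 <- u
  substr(u2, 12, 12) <- if (substr(u, 12, 12) == "G") "A" else "G"
  ref <- paste0(rand_dna(30), u, u, rand_dna(30))
  e1 <- 30L + 27L   # end of first unit copy
  e2 <- 30L + 54L   # end of second unit copy
  # view B: two separate insertions (a perfect and an imperfect unit copy)
  b <- variant_set(variant(e1 + 1L, e1, "", u), variant(e2 + 1L, e2, "", u2))
  # view A: one 54-bp insertion carrying both copies at a single point
  a <- variant_set(variant(e2 + 1L, e2, "", paste0(u, u2)))
  expect_false(identical(a, b))
  expect_true(sets_equivalent(ref, a, b))
  # equivalence relation sanity on randomized pairs built from one product
  for (i in 1:25) {
    r <- rand_repeaty()
    p <- sample(nchar(r) - 10L, 1L)
    ins <- substr(r, p + 1L, p + 6L)   # insert a copy of downstream sequence
    v1 <- variant_set(variant(p + 1L, p, "", ins))
    v2 <- variant_set(normalize_3prime(r, v1[[1L]]))
    expect_true(sets_equivalent(r, v1, v2))
    expect_true(sets_equivalent(r, v2, v1))
  }
})

test_that("normalize_variant shifts indels without changing the product", {
  # single-base deletion in a T run shifts to the run's 3' end
  v <- variant(2, 2, "T", "")
  n <- normalize_3prime("ATTTG", v)
  expect_identical(n$start, 4L)
  expect_identical(oracle_rightmost_del("ATTTG", 2L, 2L)$start, 4L)
  # non-repetitive context: unchanged
  v2 <- variant(2, 2, "C", "")
  expect_identical(normalize_3prime("ACGT", v2)$start, 2L)
  # dinucleotide insertion just before an (AG)x4 tract lands at its 3' end
  r <- "TT AGAGAGAG CC"; r <- gsub(" ", "", r)
  vi <- variant(3, 2, "", "AG")
  ni <- normalize_3prime(r, vi)
  expect_identical(ni$start - 1L, 10L)
  # idempotence and left-shift counterpart (back before the tract)
  expect_identical(normalize_3prime(r, ni), ni)
  expect_identical(normalize_variant(r, ni, "left")$start, 3L)
  expect_identical(oracle_rightmost_ins(r, 2L, "AG")$start, ni$start)
})

test_that("normalization agrees with the enumeration oracle on random repeats", {
  set.seed(101)
  for (i in 1:60) {
    r <- rand_repeaty()
    L <- nchar(r)
    if (runif(1) < 0.5) {
      w <- sample(1:5, 1)
      s <- sample(L - w, 1)
      v <- variant(s, s + w - 1L, substr(r, s, s + w - 1L), "")
      got <- normalize_3prime(r, v)
      exp <- oracle_rightmost_del(r, s, s + w - 1L)
    } else {
      p <- sample(0:(L - 6L), 1)
      ins <- substr(r, p + 1L, p + sample(1:5, 1))
      if (nchar(ins) == 0L) next
      v <- variant(p + 1L, p, "", ins)
      got <- normalize_3prime(r, v)
      exp <- oracle_rightmost_ins(r, p, ins)
    }
    expect_identical(got$start, exp$start)
    expect_true(sets_equivalent(r, variant_set(v), variant_set(got)))
  }
})

test_that("classify_dup recognizes tandem duplications and nothing else", {
  r <- "TTGAGCC"
  d <- classify_dup(r, variant(6, 5, "", "GAG"))
  expect_identical(d$kind, "dup")
  expect_identical(attr(d, "dup_start"), 3L)
  s <- classify_dup(r, variant(6, 5, "", "TTT"))
  expect_identical(s$kind, "ins")
  # insertion longer than the 5' context is never a dup
  expect_identical(classify_dup("GAG", variant(4, 3, "", "GAGG"))$kind, "ins")
  # 27-bp insertion matching the preceding 27-mer in a tandem tract
  set.seed(5)
  u <- rand_dna(27)
  r2 <- paste0(rand_dna(10), u, u, rand_dna(10))
  d2 <- classify_dup(r2, variant(65, 64, "", u))
  expect_identical(d2$kind, "dup")
  expect_identical(attr(d2, "dup_start"), 38L)
  # re-expanding the dup to ins form is sequence-identical
  expect_true(sets_equivalent(r2, variant_set(variant(65, 64, "", u)),
                              variant_set(d2)))
})

test_that("to_hgvs_c renders coding, intronic and 3'UTR forms", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  L <- nchar(ref$plus_seq)
  st <- attr(ref, "structure")
  # a 2-bp deletion placed so that its coding labels are computable by hand:
  # cseq position q maps to c.(anchor + q - coding_start)
  q <- st$coding[1] + (2790L - 1753L)
  amp_e <- L - q + 1L          # amp position of cseq q
  v <- variant(amp_e - 1L, amp_e,
               substr(ref$plus_seq, amp_e - 1L, amp_e), "")
  hg <- to_hgvs_c(v, cmap, ref$plus_seq)
  expect_match(hg, "^c\\.(\\d+)_(\\d+)del$")
  # the 3'-shifted labels can only move to higher c numbers
  nums <- as.integer(strsplit(sub("^c\\.", "", sub("del$", "", hg)), "_")[[1]])
  expect_true(nums[1] >= 2790L && nums[2] == nums[1] + 1L)
  # intronic SNV: offsets count toward the coding anchor
  qi <- st$intron[2]            # adjacent to coding start, offset -1
  ampi <- L - qi + 1L
  refb <- substr(ref$plus_seq, ampi, ampi)
  cb <- revcomp(refb)
  alt <- if (cb == "A") "G" else "A"
  vi <- variant(ampi, ampi, refb, revcomp(alt))
  expect_identical(to_hgvs_c(vi, cmap, ref$plus_seq),
                   paste0("c.1753-1", cb, ">", alt))
  # 3'UTR single-base deletion carries the deleted base, c.*N style
  qu <- st$utr3[1] + 9L
  ampu <- L - qu + 1L
  vu <- variant(ampu, ampu, substr(ref$plus_seq, ampu, ampu), "")
  expect_match(to_hgvs_c(vu, cmap, ref$plus_seq), "^c\\.\\*\\d+del[ACGT]$")
  # unmappable: insertion outside every segment cannot happen here, but a
  # position outside the map must error
  seg <- cmap$segments
  expect_error(orf15asm:::.amp_pos_to_label(0L, cmap), "unmappable")
})

test_that("references round-trip through FASTA + YAML config", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  fa <- tempfile(fileext = ".fa"); yml <- tempfile(fileext = ".yaml")
  write_reference(ref, cmap, fa, yml)
  back <- read_reference(fa, yml)
  expect_identical(back$ref$plus_seq, ref$plus_seq)
  expect_identical(back$ref$start, ref$start)
  expect_identical(back$ref$primer_rev, ref$primer_rev)
  expect_identical(back$cmap$orientation, cmap$orientation)
  expect_identical(back$cmap$segments$c_anchor, cmap$segments$c_anchor)
  # the reloaded map emits identical HGVS
  truths <- spike_standard_truthsets(ref)
  v <- truths$del2[[1L]]
  expect_identical(to_hgvs_c(v, back$cmap, back$ref$plus_seq),
                   to_hgvs_c(v, cmap, ref$plus_seq))
  unlink(c(fa, yml))
})

test_that("parse_hgvs_c inverts to_hgvs_c and rejects garbage", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  truths <- spike_standard_truthsets(ref)
  for (nm in names(truths)) {
    v <- truths[[nm]][[1L]]
    hg <- to_hgvs_c(v, cmap, ref$plus_seq)
    back <- parse_hgvs_c(hg, cmap, ref$plus_seq)
    expect_true(sets_equivalent(ref$plus_seq, variant_set(v), variant_set(back)),
                info = nm)
    expect_identical(to_hgvs_c(back, cmap, ref$plus_seq), hg, info = nm)
  }
  expect_error(parse_hgvs_c("p.Glu931GlyfsTer147", cmap, ref$plus_seq), "parse")
  expect_error(parse_hgvs_c("c.banana", cmap, ref$plus_seq), "parse")
})

test_that("print/parse/apply round trip holds for random variants", {
  ref <- fix_ref(11L)
  cmap <- default_coordinate_map(ref)
  seq <- ref$plus_seq
  L <- nchar(seq)
  st <- attr(ref, "structure")
  set.seed(303)
  n_ok <- 0L
  for (i in 1:120) {
    # random small edit fully inside the mapped region, amp coords
    s <- sample(30:(L - 40L), 1)
    type <- sample(c("snv", "del", "ins", "delins"), 1)
    v <- switch(type,
      snv = {
        rb <- substr(seq, s, s)
        variant(s, s, rb, sample(setdiff(c("A", "C", "G", "T"), rb), 1))
      },
      del = {
        e <- s + sample(0:5, 1)
        variant(s, e, substr(seq, s, e), "")
      },
      ins = variant(s + 1L, s, "", rand_dna(sample(1:8, 1))),
      delins = {
        e <- s + sample(1:4, 1)
        repeat {
          alt <- rand_dna(sample(2:6, 1))
          if (alt != substr(seq, s, e)) break
        }
        variant(s, e, substr(seq, s, e), alt)
      })
    hg <- to_hgvs_c(v, cmap, seq)
    back <- parse_hgvs_c(hg, cmap, seq)
    expect_identical(apply_variant_set(seq, variant_set(back)),
                     apply_variant_set(seq, variant_set(v)),
                     info = paste(i, hg))
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 120L)
})
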