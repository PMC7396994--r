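test_that("reads place at their source position with the right operations", {
  ref <- fix_ref()
  plus <- ref$plus_seq
  r <- substr(plus, 501, 651)
  pl <- place_read(r, ref)
  expect_true(pl$placed)
  expect_identical(pl$start, 501L)
  expect_identical(pl$ops, strrep("M", 151))
  # reverse-complement read maps to the same place on the other strand
  pl2 <- place_read(revcomp(r), ref)
  expect_true(pl2$placed)
  expect_identical(pl2$start, 501L)
  expect_identical(pl2$strand, "-")
  # one mismatch: placed with a single X column
  r3 <- r
  substr(r3, 80, 80) <- if (substr(r, 80, 80) == "A") "C" else "A"
  pl3 <- place_read(r3, ref)
  expect_identical(pl3$start, 501L)
  expect_identical(sum(strsplit(pl3$ops, "")[[1]] == "X"), 1L)
  # unrelated sequence shares no 31-mer: unplaced
  set.seed(66)
  pl4 <- place_read(rand_dna(151), ref)
  expect_false(pl4$placed)
})

test_that("pileup calling applies the allele-fraction thresholds", {
  # synthetic pileup via synthetic reads: 60/100 alt -> het, 95/100 -> hom
  ref_seq <- paste0(strrep("ACTTC", 30))
  mk_reads <- function(n_alt, n_tot, pos, alt) {
    base <- substr(ref_seq, 1, 150)
    altread <- base
    substr(altread, pos, pos) <- alt
    c(rep(altread, n_alt), rep(base, n_tot - n_alt))
  }
  bp <- baseline_params(seed_k = 31L)
  p1 <- build_pileup(mk_reads(60, 100, 75, "G"), ref_seq, bp)
  c1 <- pileup_call(p1, bp, "male")
  expect_length(c1, 1L)
  expect_identical(c1[[1]]$zygosity, "heterozygous")
  expect_identical(c1[[1]]$variant$start, 75L)
  p2 <- build_pileup(mk_reads(95, 100, 75, "G"), ref_seq, bp)
  c2 <- pileup_call(p2, bp, "male")
  expect_identical(c2[[1]]$zygosity, "hemizygous")
  expect_identical(pileup_call(p2, bp, "female")[[1]]$zygosity, "homozygous")
  # below min_depth: no call
  p3 <- build_pileup(mk_reads(6, 10, 75, "G"), ref_seq, bp)
  expect_length(pileup_call(p3, bp, "male"), 0L)
})

test_that("heterozygous calls in males are flagged as artifacts", {
  het <- structure(list(variant = variant(5, 5, "A", "G"), caller = "baseline",
                        zygosity = "heterozygous", flags = character(0)),
                   class = "variant_call")
  hemi <- structure(list(variant = variant(9, 9, "A", "G"), caller = "baseline",
                         zygosity = "hemizygous", flags = character(0)),
                    class = "variant_call")
  fl <- flag_het_in_haploid(list(het, hemi), "male")
  expect_identical(fl[[1]]$flags, "het_in_male")
  expect_length(fl[[2]]$flags, 0L)
  expect_length(flag_het_in_haploid(list(het), "female")[[1]]$flags, 0L)
  expect_warning(flag_het_in_haploid(list(het), "unknown"), "unknown")
})

test_that("concordance quality is high iff per-sample presence is identical", {
  ref <- fix_ref()
  mkcall <- function(pos, alt, zyg) {
    rb <- substr(ref$plus_seq, pos, pos)
    structure(list(variant = variant(pos, pos, rb, alt, zyg), caller = "x",
                   zygosity = zyg, flags = character(0)),
              class = "variant_call")
  }
  alt_at <- function(pos) if (substr(ref$plus_seq, pos, pos) == "A") "G" else "A"
  vA <- function(zyg = "hemizygous") mkcall(500, alt_at(500), zyg)
  vB <- function(zyg = "hemizygous") mkcall(900, alt_at(900), zyg)
  sexes <- c(s1 = "male", s2 = "male", s3 = "female")
  # variant A in the same two samples by both pipelines -> high
  base <- list(s1 = list(vA()), s2 = list(vA(), vB("heterozygous")), s3 = list())
  novel <- list(s1 = list(vA()), s2 = list(vA()), s3 = list())
  tab <- concordance_table(base, novel, sexes, ref)
  keyA <- orf15asm:::.call_key(vA(), ref)
  keyB <- orf15asm:::.call_key(vB(), ref)
  expect_identical(tab$quality[tab$variant_key == keyA], "high")
  expect_identical(tab$n_baseline[tab$variant_key == keyA], 2L)
  expect_identical(tab$n_novel[tab$variant_key == keyA], 2L)
  # variant B called only by the baseline, heterozygous in a male -> low
  expect_identical(tab$quality[tab$variant_key == keyB], "low")
  expect_identical(tab$n_het[tab$variant_key == keyB], 1L)
  expect_identical(tab$n_het_male[tab$variant_key == keyB], 1L)
  expect_identical(tab$n_novel[tab$variant_key == keyB], 0L)
  # symmetric in sample order and deterministic
  perm <- c("s3", "s1", "s2")
  tab2 <- concordance_table(base[perm], novel[perm], sexes, ref)
  expect_identical(tab, tab2)
  # absent everywhere: no row
  expect_identical(nrow(concordance_table(list(s1 = list()), list(s1 = list()),
                                          sexes, ref)), 0L)
  # the same edit under two namings matches through left alignment
  plus <- ref$plus_seq
  tt <- regexpr("CTTTC", plus, fixed = TRUE)
  s <- tt + 1L
  v_right <- structure(list(variant = variant(s + 2L, s + 2L,
                                              substr(plus, s + 2L, s + 2L), "",
                                              "hemizygous"),
                            zygosity = "hemizygous", flags = character(0)),
                       class = "variant_call")
  v_left <- structure(list(variant = variant(s, s, substr(plus, s, s), "",
                                             "hemizygous"),
                           zygosity = "hemizygous", flags = character(0)),
                      class = "variant_call")
  tab3 <- concordance_table(list(s1 = list(v_left)), list(s1 = list(v_right)),
                            c(s1 = "male"), ref)
  expect_identical(nrow(tab3), 1L)
  expect_identical(tab3$quality, "high")
})

test_that("a large in-repeat duplication breaks the baseline but not assembly", {
  ref <- fix_ref()
  cmap <- default_coordinate_map(ref)
  truths <- spike_standard_truthsets(ref)
  cfg <- pipeline_config()
  sim <- simulate_sample(ref, truths$dup27, cfg$sim, seed = 101)
  reads <- c(sim$r1, sim$r2)
  bc <- pileup_call(build_pileup(reads, ref, cfg$baseline), cfg$baseline, "male")
  spurious_het <- sum(vapply(bc, function(x)
    x$zygosity == "heterozygous" && x$variant$kind == "SNV", logical(1)))
  expect_gte(spurious_het, 1L)
  rep <- run_sample(reads = reads, sample_id = "dup27", sex = "male",
                    ref = ref, cmap = cmap, config = cfg)
  expect_true(recovered_exactly(rep, ref, truths$dup27))
  expect_length(rep$calls_final, 1L)
})
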