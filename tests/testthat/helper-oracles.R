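# Shared fixtures and independent oracles used across test files.

# one reference + map reused by many tests (cheap to build, deterministic)
fix_ref <- function(seed = 7L) synthesize_reference(repeat_model(), seed = seed)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# repeat-rich random sequence: short units repeated, interleaved with random
rand_repeaty <- function(n_units = 8L, unit_len = 3L:6L, reps = 2L:5L) {
  parts <- replicate(n_units, {
    u <- rand_dna(sample(unit_len, 1))
    paste(rep(u, sample(reps, 1)), collapse = "")
  })
  paste0(rand_dna(5), paste(parts, collapse = ""), rand_dna(5))
}

# enumeration oracle for 3'-shifting: the equivalent representation with the
# highest start coordinate, found by trying every candidate position and
# comparing edited products directly
oracle_rightmost_del <- function(ref, s, e) {
  w <- e - s + 1L
  target <- apply_variant_set(ref, variant_set(variant(s, e, substr(ref, s, e), "")))
  best <- NULL
  for (cs in seq_len(nchar(ref) - w + 1L)) {
    v <- variant(cs, cs + w - 1L, substr(ref, cs, cs + w - 1L), "")
    if (apply_variant_set(ref, variant_set(v)) == target) best <- v
  }
  best
}

oracle_rightmost_ins <- function(ref, p, ins) {
  w <- nchar(ins)
  L <- nchar(ref)
  target <- apply_variant_set(ref, variant_set(variant(p + 1L, p, "", ins)))
  best <- NULL
  for (cp in 0:L) {
    cand <- substr(target, cp + 1L, cp + w)
    if (nchar(cand) < w) next
    v <- variant(cp + 1L, cp, "", cand)
    if (apply_variant_set(ref, variant_set(v)) == target) best <- v
  }
  best
}

# brute-force check whether a (3'-shifted) insertion is a tandem duplication
oracle_is_dup <- function(ref, v) {
  p <- v$start - 1L
  n <- nchar(v$alt_allele)
  p >= n && substr(ref, p - n + 1L, p) == v$alt_allele
}

# error-free tiling read pairs over a sequence (each read emitted in both
# mate orientations, duplicated so no k-mer falls under a count prune of 1)
tiling_reads <- function(seq, read_len = 151L, step = 7L) {
  L <- nchar(seq)
  if (L < read_len) stop("sequence shorter than read length")
  starts <- unique(c(seq(1L, L - read_len + 1L, by = step), L - read_len + 1L))
  fwd <- substring(seq, starts, starts + read_len - 1L)
  c(fwd, revcomp(fwd))
}

run_class_sample <- function(ref, cmap, truth, seed, cfg = pipeline_config()) {
  sim <- simulate_sample(ref, truth, cfg$sim, seed = seed)
  run_sample(reads = c(sim$r1, sim$r2), sample_id = paste0("s", seed),
             sex = "male", ref = ref, cmap = cmap, config = cfg)
}

recovered_exactly <- function(report, ref, truth) {
  identical(report$status, "resolved") &&
    sets_equivalent(ref$plus_seq,
                    variant_set(lapply(report$calls_final, `[[`, "variant")),
                    truth)
}
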