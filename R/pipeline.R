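# End-to-end orchestration: FASTQ -> assembly rounds -> contig selection ->
# alignment -> calls -> consequences -> prioritization -> annotation ->
# VCF + report, plus cohort runs with the baseline comparator.

#' Pipeline configuration
#'
#' One object governs all modules. Defaults are the documented operating
#' point: selection thresholds as printed, round-1 k list (21..127), affine
#' alignment scores, allele-fraction baseline caller, simulation at 1000x
#' with 2x151 reads and 273 bp fragments.
#'
#' @param thresholds a `selection_thresholds`.
#' @param assembly an `assembly_params`.
#' @param align an `align_params`.
#' @param baseline a `baseline_params`.
#' @param sim a `simulation_config`.
#' @param seed integer master seed.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(thresholds = selection_thresholds(),
                            assembly = assembly_params(),
                            align = align_params(),
                            baseline = baseline_params(),
                            sim = simulation_config(),
                            seed = 1L) {
  structure(list(thresholds = thresholds, assembly = assembly, align = align,
                 baseline = baseline, sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @return `write_pipeline_config` returns the path; `read_pipeline_config`
#'   the config.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (part in c("thresholds", "assembly", "align", "baseline", "sim")) {
    if (!is.null(y[[part]]))
      for (nm in names(y[[part]])) cfg[[part]][[nm]] <- y[[part]][[nm]]
  }
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  cfg
}

#' Validate a sample manifest
#'
#' @param df data.frame with columns sample_id, sex (male/female/unknown),
#'   r1, r2 (FASTQ paths).
#' @return the validated manifest.
#' @export
sample_manifest <- function(df) {
  need <- c("sample_id", "sex", "r1", "r2")
  if (!all(need %in% names(df))) stop("manifest needs columns ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id in manifest")
  if (!all(df$sex %in% c("male", "female", "unknown")))
    stop("sex must be male, female or unknown")
  paths <- c(df$r1, df$r2)
  if (anyDuplicated(paths)) stop("manifest FASTQ paths must be distinct")
  structure(df, class = c("sample_manifest", "data.frame"))
}

# alignment-implied reconstruction: uncovered ref prefix + aligned query + suffix
.expected_haplotype <- function(aln) {
  r <- strsplit(aln$ref_row, "")[[1]]
  q <- strsplit(aln$query_row, "")[[1]]
  n <- length(r)
  gap <- r == "-" | q == "-"
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  tail <- n + 1L
  while (tail > 1L && gap[tail - 1L]) tail <- tail - 1L
  core <- if (tail > lead + 1L) (lead + 1L):(tail - 1L) else integer(0)
  lead_ref <- paste(r[seq_len(lead)][r[seq_len(lead)] != "-"], collapse = "")
  tail_ref <- if (tail <= n) paste(r[tail:n][r[tail:n] != "-"], collapse = "") else ""
  core_q <- paste(q[core][q[core] != "-"], collapse = "")
  paste0(lead_ref, core_q, tail_ref)
}

#' Run the assembly pipeline on one sample
#'
#' @param reads character vector of reads, or NULL to read `r1`/`r2`.
#' @param r1,r2 FASTQ paths (used when `reads` is NULL).
#' @param sample_id sample name.
#' @param sex "male", "female" or "unknown" (zygosity rule: one selected
#'   contig is hemizygous in males, unknown in females; a second passing
#'   satisfactory contig marks both as heterozygous candidates).
#' @param ref an `amplicon_reference`.
#' @param cmap a `coordinate_map`.
#' @param config a `pipeline_config`.
#' @param freq_table optional frequency data.frame
#'   (see [read_frequency_table()]).
#' @param out_dir optional output directory for VCF + report.
#' @return a `sample_report`.
#' @export
run_sample <- function(reads = NULL, r1 = NULL, r2 = NULL,
                       sample_id = "sample",
                       sex = c("unknown", "male", "female"),
                       ref, cmap, config = pipeline_config(),
                       freq_table = NULL, out_dir = NULL) {
  sex <- match.arg(sex)
  if (is.null(reads)) {
    fq <- read_fastq_pair(r1, r2)
    reads <- c(fq$r1, fq$r2)
  }
  rr <- run_assembly_rounds(reads, ref, config$thresholds, config$assembly)
  rep0 <- list(sample_id = sample_id, sex = sex, round_log = rr$log,
               contig = rr$contig, calls_raw = list(), calls_final = list(),
               calls_prioritized = list(), status = "failed")
  if (is.null(rr$contig)) {
    rep0$status <- "unresolved: no satisfactory contig after round 3"
    return(structure(rep0, class = "sample_report"))
  }
  aln <- global_align(rr$contig$seq, ref$plus_seq, config$align)
  raw <- calls_from_alignment(aln)
  zyg <- if (sex == "male") "hemizygous" else "unknown"
  finalized <- finalize_calls(raw, ref, cmap, zygosity = zyg,
                              caller = "assembly", support = rr$contig$id)
  # hard invariant: the finalized set reapplied to the reference reproduces
  # the aligned haplotype exactly
  expected <- .expected_haplotype(aln)
  got <- apply_variant_set(ref$plus_seq, variant_set(raw))
  if (!identical(got, expected))
    stop("internal consistency failure: calls do not reproduce the contig")
  if (!is.null(freq_table)) finalized <- annotate_frequency(finalized, freq_table)
  prio <- prioritize(finalized)
  rep0$calls_raw <- raw
  rep0$calls_final <- finalized
  rep0$calls_prioritized <- prio
  rep0$alignment_score <- aln$score
  rep0$status <- "resolved"
  out <- structure(rep0, class = "sample_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(finalized, ref, file.path(out_dir, paste0(sample_id, ".vcf")),
              sample_id)
    write_sample_report(out, file.path(out_dir, paste0(sample_id, "_report.yaml")))
  }
  out
}

#' Serialize a sample report as structured text
#'
#' @param report a `sample_report`.
#' @param path YAML path.
#' @export
write_sample_report <- function(report, path) {
  calls <- function(cl) lapply(cl, function(x)
    list(hgvs_c = x$hgvs_c, p = x$p_notation, consequence = x$consequence,
         zygosity = x$zygosity, pos = x$vcf$pos, ref = x$vcf$ref,
         alt = x$vcf$alt, frequency = x$frequency, rsid = x$rsid,
         flags = as.list(x$flags)))
  yaml::write_yaml(list(
    sample_id = report$sample_id, sex = report$sex, status = report$status,
    rounds_used = report$round_log$rounds_used,
    contig = if (is.null(report$contig)) NULL else
      list(id = report$contig$id, length = report$contig$length,
           mean_cov = report$contig$mean_cov),
    finalized = calls(report$calls_final),
    prioritized = calls(report$calls_prioritized)), path)
  invisible(path)
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Sample", x$sample_id, "(", x$sex, "):", x$status, "\n")
  print(x$round_log)
  if (length(x$calls_final)) {
    cat("Finalized calls:\n")
    for (cl in x$calls_final) print(cl)
  }
  if (length(x$calls_prioritized)) {
    cat("Prioritized (frameshift/nonsense):\n")
    for (cl in x$calls_prioritized) print(cl)
  } else cat("No prioritized calls.\n")
  invisible(x)
}

#' Run both pipelines over a cohort and build the concordance table
#'
#' Per sample: the assembly pipeline (`run_sample`) and the baseline
#' mapping/pileup caller, with heterozygous-in-male flagging. Per-sample
#' failures are isolated; the cohort run continues. The summary counts
#' resolved/unresolved samples and prioritized (pathogenic-class) findings,
#' and every summary number is recomputable from the per-sample reports.
#'
#' @param manifest a `sample_manifest` (or data.frame with its columns).
#'   Paths may be omitted when `reads_by_sample` supplies in-memory reads.
#' @param ref an `amplicon_reference`.
#' @param cmap a `coordinate_map`.
#' @param config a `pipeline_config`.
#' @param freq_table optional frequency table.
#' @param reads_by_sample optional named list (sample id -> character vector
#'   of reads) overriding FASTQ paths.
#' @param out_dir optional output directory.
#' @return list with `reports`, `baseline_calls`, `concordance`, `summary`.
#' @export
run_cohort <- function(manifest, ref, cmap, config = pipeline_config(),
                       freq_table = NULL, reads_by_sample = NULL,
                       out_dir = NULL) {
  manifest <- sample_manifest(as.data.frame(manifest))
  reports <- list(); basecalls <- list()
  novel_by_sample <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    sex <- manifest$sex[i]
    res <- tryCatch({
      reads <- if (!is.null(reads_by_sample)) reads_by_sample[[sid]] else NULL
      rep <- run_sample(reads = reads, r1 = manifest$r1[i], r2 = manifest$r2[i],
                        sample_id = sid, sex = sex, ref = ref, cmap = cmap,
                        config = config, freq_table = freq_table,
                        out_dir = out_dir)
      if (is.null(reads)) {
        fq <- read_fastq_pair(manifest$r1[i], manifest$r2[i])
        reads <- c(fq$r1, fq$r2)
      }
      bc <- pileup_call(build_pileup(reads, ref, config$baseline),
                        config$baseline, sex)
      bc <- flag_het_in_haploid(bc, sex)
      list(report = rep, baseline = bc)
    }, error = function(e) {
      list(report = structure(list(sample_id = sid, sex = sex,
                                   status = paste("error:", conditionMessage(e)),
                                   calls_final = list(),
                                   calls_prioritized = list()),
                              class = "sample_report"),
           baseline = list())
    })
    reports[[sid]] <- res$report
    basecalls[[sid]] <- res$baseline
    novel_by_sample[[sid]] <- res$report$calls_final
  }
  sexes <- setNames(manifest$sex, manifest$sample_id)
  conc <- concordance_table(basecalls, novel_by_sample, sexes, ref)
  summary <- list(
    n_samples = nrow(manifest),
    n_resolved = sum(vapply(reports, function(r) identical(r$status, "resolved"),
                            logical(1))),
    n_with_prioritized = sum(vapply(reports, function(r)
      length(r$calls_prioritized) > 0L, logical(1))),
    n_unique_variants = length(unique(unlist(lapply(reports, function(r)
      vapply(r$calls_final, `[[`, character(1), "hgvs_c"))))))
  list(reports = reports, baseline_calls = basecalls, concordance = conc,
       summary = summary)
}
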