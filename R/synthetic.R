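#' Design of a synthetic lineage-tracing study
#'
#' Bundles every knob of the synthetic-data generator: clonal sampling
#' times and per-timepoint clone quotas for each genotype (defaults mirror
#' a dorsal-epidermis lineage-tracing design with sampling at 1.5, 3, 6
#' and 12 weeks and tens to hundreds of scored clones per timepoint),
#' the genotype parameter sets, the dilution-chase design, and the
#' composition of the planted variant tables.
#'
#' @param times clonal sampling times in weeks.
#' @param clones_per_time named list of integer vectors (one per genotype,
#'   same length as `times`): detected clones to emit per timepoint.
#' @param animals_per_time animals per timepoint (clones assigned
#'   round-robin).
#' @param params named list of [sp_params()] per genotype.
#' @param dilution a [dilution_config()] for the label-dilution chase.
#' @param variants list describing the planted variant table: `n_mice`,
#'   per-mouse counts `n_true_irr`, `n_true_unexp` (true somatic variants
#'   unique to one biopsy), `n_shared` (germline-like variants planted in
#'   both biopsies), `n_artifact_p` (large p-value artifacts) and
#'   `n_artifact_strand` (single-strand artifacts with small p-values).
#' @return An object of class `study_design`.
#' @export
study_design <- function(times = c(1.5, 3, 6, 12),
                         clones_per_time = list(wt = c(93, 106, 181, 183),
                                                mut = c(50, 75, 199, 196)),
                         animals_per_time = 3,
                         params = list(wt = sp_params(delta = 0),
                                       mut = sp_params(delta = 0.25)),
                         dilution = dilution_config(),
                         variants = list(n_mice = 5, n_true_irr = 12,
                                         n_true_unexp = 2, n_shared = 5,
                                         n_artifact_p = 6,
                                         n_artifact_strand = 4)) {
  stopifnot(all(times >= 0), length(clones_per_time) == length(params),
            all(names(clones_per_time) %in% names(params)),
            all(vapply(clones_per_time, length, 1L) == length(times)),
            animals_per_time >= 1)
  for (p in params) stopifnot(inherits(p, "sp_params"))
  structure(list(times = times, clones_per_time = clones_per_time,
                 animals_per_time = animals_per_time, params = params,
                 dilution = dilution, variants = variants),
            class = "study_design")
}

#' Generate a clone-count table with known ground truth
#'
#' Simulates independent clones from the single-progenitor process at each
#' sampling time, keeps only detected clones (basal size >= 1, the
#' wholemount scoring rule), and resamples until each per-timepoint quota
#' is met.
#'
#' @param design a [study_design()] object.
#' @param seed integer seed.
#' @return List with `clones` (a clone table, see [read_clone_table()])
#'   and `truth` (named list of generating parameter values per genotype).
#' @export
gen_clone_table <- function(design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in names(design$clones_per_time)) {
    par <- design$params[[g]]
    for (k in seq_along(design$times)) {
      quota <- design$clones_per_time[[g]][k]
      if (quota == 0) next
      tt <- design$times[k]
      got <- data.frame(n_p = integer(0), n_d = integer(0), n_s = integer(0))
      tried <- 0L
      while (nrow(got) < quota) {
        batch <- max(2L * (quota - nrow(got)), 50L)
        sim <- simulate_clone_final(par, tt, batch)
        tried <- tried + batch
        det <- sim[sim$n_p + sim$n_d >= 1, , drop = FALSE]
        got <- rbind(got, det)
        if (tried >= 200L * quota && nrow(got) < quota * 1e-4 * tried / quota)
          stop("detection probability below 1e-4 at t = ", tt)
        if (tried > 1e7) stop("detection probability too low at t = ", tt)
      }
      got <- got[seq_len(quota), ]
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = paste0(g, "_A", (seq_len(quota) %% design$animals_per_time) + 1L),
        genotype = g, time_weeks = tt,
        n_basal = got$n_p + got$n_d, n_suprabasal = got$n_s)
    }
  }
  clones <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(0), genotype = character(0),
               time_weeks = numeric(0), n_basal = integer(0),
               n_suprabasal = integer(0))
  rownames(clones) <- NULL
  truth <- list()
  for (g in names(design$params))
    for (f in c("r", "lam", "delta", "gamma", "mu"))
      truth[[paste0(g, "_", f)]] <- design$params[[g]][[f]]
  list(clones = clones, truth = truth)
}

#' Generate a label-dilution intensity table with known ground truth
#'
#' @inheritParams gen_clone_table
#' @return List with `samples` (see [simulate_dilution()]) and `truth`.
#' @export
gen_dilution_data <- function(design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  samples <- simulate_dilution(design$dilution, seed = seed)
  cfg <- design$dilution
  list(samples = samples,
       truth = list(lam = cfg$lam, i0_log2 = cfg$i0_log2,
                    noise_sd = cfg$noise_sd,
                    slow_fraction = cfg$slow_fraction,
                    lam_slow = cfg$lam_slow))
}

#' Generate a variant table with known filtering truth
#'
#' Plants, per mouse: true somatic variants unique to one biopsy (small
#' p-values, both strands supported), germline-like variants shared
#' between the paired biopsies, large-p artifacts and single-strand
#' artifacts.  p-values are placed far from the q-value threshold so which
#' records survive [run_filter_pipeline()] is decided by construction and
#' recorded in the truth table; true variants are predominantly C>T
#' (UV signature), artifacts have uniform substitution classes.
#'
#' @inheritParams gen_clone_table
#' @return List with `records` (a variant table) and `truth` (data frame
#'   `chrom, pos, ref, alt, biopsy_id, planted_class, should_survive`).
#' @export
gen_variant_table <- function(design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  v <- design$variants
  chroms <- paste0("chr", 1:19)
  pos_counter <- 0L
  # p_uv: probability of a UV-signature change (C>T on either strand);
  # true somatic variants are predominantly UV-type, artifacts are not
  new_site <- function(p_uv = 0.25) {
    if (runif(1) < p_uv) {
      if (runif(1) < 0.5) c(ref = "C", alt = "T") else c(ref = "G", alt = "A")
    } else {
      repeat {
        ra <- sample(c("A", "C", "G", "T"), 2)
        if (ra[1] != ra[2]) return(c(ref = ra[1], alt = ra[2]))
      }
    }
  }
  recs <- list()
  truths <- list()
  emit <- function(mouse, biopsy, exposure, class, p, fwd, rev, site, pos) {
    rec <- data.frame(chrom = sample(chroms, 1), pos = pos,
                      ref = site[["ref"]], alt = site[["alt"]],
                      biopsy_id = biopsy, mouse_id = mouse,
                      exposure = exposure, p_value = p,
                      fwd_reads = fwd, rev_reads = rev)
    recs[[length(recs) + 1L]] <<- rec
    truths[[length(truths) + 1L]] <<- cbind(
      rec[c("chrom", "pos", "ref", "alt", "biopsy_id")],
      planted_class = class,
      should_survive = class %in% c("true_irr", "true_unexp"))
  }
  for (m in seq_len(v$n_mice)) {
    mouse <- paste0("M", m)
    b_irr <- paste0(mouse, "_irr"); b_un <- paste0(mouse, "_unexp")
    small_p <- function() 10^runif(1, -8, -6)
    for (i in seq_len(v$n_true_irr))
      emit(mouse, b_irr, "irradiated", "true_irr", small_p(),
           1 + rpois(1, 4), 1 + rpois(1, 4), new_site(p_uv = 0.9),
           (pos_counter <- pos_counter + 1L) * 10L)
    for (i in seq_len(v$n_true_unexp))
      emit(mouse, b_un, "unexposed", "true_unexp", small_p(),
           1 + rpois(1, 4), 1 + rpois(1, 4), new_site(p_uv = 0.9),
           (pos_counter <- pos_counter + 1L) * 10L)
    for (i in seq_len(v$n_shared)) {
      site <- new_site()
      pos <- (pos_counter <- pos_counter + 1L) * 10L
      chrom <- sample(chroms, 1)
      for (b in list(c(b_irr, "irradiated"), c(b_un, "unexposed"))) {
        rec <- data.frame(chrom = chrom, pos = pos, ref = site[["ref"]],
                          alt = site[["alt"]], biopsy_id = b[1],
                          mouse_id = mouse, exposure = b[2],
                          p_value = small_p(), fwd_reads = 1 + rpois(1, 4),
                          rev_reads = 1 + rpois(1, 4))
        recs[[length(recs) + 1L]] <- rec
        truths[[length(truths) + 1L]] <- cbind(
          rec[c("chrom", "pos", "ref", "alt", "biopsy_id")],
          planted_class = "shared", should_survive = FALSE)
      }
    }
    for (i in seq_len(v$n_artifact_p))
      emit(mouse, sample(c(b_irr, b_un), 1),
           if (i %% 2) "irradiated" else "unexposed", "artifact_p",
           runif(1, 0.5, 1), 1 + rpois(1, 4), 1 + rpois(1, 4), new_site(),
           (pos_counter <- pos_counter + 1L) * 10L)
    for (i in seq_len(v$n_artifact_strand)) {
      fwd <- if (i %% 2) 2 + rpois(1, 4) else 0
      rev <- if (i %% 2) 0 else 2 + rpois(1, 4)
      emit(mouse, b_irr, "irradiated", "artifact_strand", small_p(),
           fwd, rev, new_site(),
           (pos_counter <- pos_counter + 1L) * 10L)
    }
  }
  records <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  rownames(records) <- rownames(truth) <- NULL
  # exposure label used by artifact_p records must match the biopsy
  records$exposure <- ifelse(grepl("_irr$", records$biopsy_id),
                             "irradiated", "unexposed")
  list(records = validate_variant_table(records), truth = truth)
}

#' Emit a complete synthetic study bundle to disk
#'
#' Writes the clone table, dilution table and variant table with their
#' truth sidecar files (shared basename, `_truth` suffix).  Regeneration
#' with the same design and seed is byte-identical.
#'
#' @inheritParams gen_clone_table
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
make_synthetic_bundle <- function(design, dir, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  cl <- gen_clone_table(design)
  di <- gen_dilution_data(design)
  va <- gen_variant_table(design)
  paths <- c(
    clones = file.path(dir, "clones.tsv"),
    clones_truth = file.path(dir, "clones_truth.txt"),
    dilution = file.path(dir, "dilution.tsv"),
    dilution_truth = file.path(dir, "dilution_truth.txt"),
    variants = file.path(dir, "variants.tsv"),
    variants_truth = file.path(dir, "variants_truth.tsv"))
  write_clone_table(cl$clones, paths["clones"])
  write_kv(c(cl$truth, list(seed = seed)), paths["clones_truth"])
  write.table(di$samples, paths["dilution"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_kv(c(di$truth, list(seed = seed)), paths["dilution_truth"])
  write_variant_table(va$records, paths["variants"])
  write.table(va$truth, paths["variants_truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
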