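# per-stage RNG substream: stable hash of the stage name folded into the
# global seed, kept below 2^31
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(global_seed) %% 100000L) * 10007L + h %% 10007L
}

#' Pipeline configuration
#'
#' @param outdir Run directory for all stage outputs.
#' @param seed Global seed; per-stage substreams are derived from it by a
#'   stable hash of the stage name, so stages can be re-run in isolation.
#' @param sim A `sim_config` (or NULL to load an existing cohort from
#'   `genotype_table`/`alleles`).
#' @param genotype_table,alleles Input paths when not simulating.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "phase", "ligands", "selection", "diversity", "coevolve")`.
#' @param scan Parameters for the co-evolution stage: list with `hla_genes`,
#'   `kir_genes`, `alpha`, `n_perm`.
#' @param tajima_reps Coalescent replicates for Tajima significance.
#' @param fnd_sims Null configurations per Slatkin/F_nd test.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = NULL,
                            genotype_table = NULL, alleles = NULL,
                            stages = c("simulate", "phase", "ligands",
                                       "selection", "diversity", "coevolve"),
                            scan = list(hla_genes = c("HLA-B", "HLA-C"),
                                        kir_genes = c("KIR3DL1", "KIR2DL1"),
                                        alpha = 0.05, n_perm = 1000L),
                            tajima_reps = 2000L, fnd_sims = 2000L) {
  structure(list(outdir = outdir, seed = seed, sim = sim,
                 genotype_table = genotype_table, alleles = alleles,
                 stages = stages, scan = scan, tajima_reps = tajima_reps,
                 fnd_sims = fnd_sims),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> phase -> ligands -> selection -> diversity ->
#' coevolve over a run directory, writing each stage's tables plus a JSON
#' manifest (package version, global seed, per-stage seeds, input hashes).
#' The run is deterministic given the seed and inputs. A stage failure stops
#' the run naming the failing stage; completed stage outputs are preserved.
#'
#' @param cfg A `pipeline_config`.
#' @return Object of class `pipeline_report` summarising each stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = character(0))
  manifest <- list(package = "kirhla",
                   version = as.character(utils::packageVersion("kirhla")),
                   seed = cfg$seed,
                   stage_seeds = sapply(cfg$stages, stage_seed,
                                        global_seed = cfg$seed))
  cohort <- NULL; phased <- NULL
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  for (st in cfg$stages) {
    sseed <- stage_seed(cfg$seed, st)
    if (st == "simulate") {
      run_stage(st, function() {
        sim_cfg <- cfg$sim
        if (is.null(sim_cfg)) stop("no sim_config supplied")
        sim_cfg$seed <- sseed
        sim <- simulate_cohort(sim_cfg)
        write_simulated_cohort(sim, cfg$outdir)
        cohort <<- sim$cohort
        report$n_individuals <<- nrow(sim$cohort$individuals)
      })
    } else if (st == "phase") {
      run_stage(st, function() {
        if (is.null(cohort)) {
          if (is.null(cfg$genotype_table)) stop("no cohort available")
          cohort <<- load_cohort(cfg$genotype_table, cfg$alleles, quiet = TRUE)
        }
        phased <<- phase_cohort(cohort)
        rows <- list()
        for (locus in names(phased$models)) {
          for (id in phased$individuals$id) {
            r <- phased$phased[[locus]][[id]]
            for (h in 1:2) rows[[length(rows) + 1L]] <- data.frame(
              individual = id, locus = locus, hap_index = h,
              alleles = hap_key(r[[c("h1", "h2")[h]]]),
              resolution = r$resolution, stringsAsFactors = FALSE)
          }
        }
        write.table(do.call(rbind, rows), file.path(cfg$outdir, "haplotypes.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        cens <- list()
        for (locus in names(phased$models)) {
          cc <- haplotype_census(phased, locus)
          cens[[length(cens) + 1L]] <- cbind(locus = locus, as.data.frame(cc))
          report[[paste0("census_", locus)]] <<-
            c(n2 = attr(cc, "n2"), k = nrow(cc))
        }
        write.table(do.call(rbind, cens), file.path(cfg$outdir, "census.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      })
    } else if (st == "ligands") {
      run_stage(st, function() {
        if (is.null(cohort)) stop("no cohort available")
        dist <- cohort_pair_distribution(cohort)
        pr <- do.call(rbind, lapply(names(dist$counts), function(id) {
          pc <- count_functional_pairs(cohort$genotypes[[id]], cohort$registry,
                                       assign_epitopes_registry(cohort$registry))
          if (pc$count) cbind(individual = id, pc$pairs) else NULL
        }))
        if (!is.null(pr))
          write.table(pr, file.path(cfg$outdir, "pairs.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(mean = dist$mean, interval = dist$interval,
                                  histogram = as.list(dist$histogram)),
                             file.path(cfg$outdir, "pair_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        report$pair_mean <<- dist$mean
      })
    } else if (st == "selection") {
      run_stage(st, function() {
        if (is.null(phased)) stop("selection stage needs phased data; run 'phase'")
        models <- read_demographic_models()
        rows <- list()
        set.seed(sseed)
        for (locus in names(phased$models)) {
          cc <- haplotype_census(phased, locus)
          model <- phased$models[[locus]]
          for (g in model$genes) {
            sp <- census_gene_spectrum(cc, g, resolution = "allotype")
            if (is.null(sp)) next
            ew <- slatkin_fnd(sp, n_sim = cfg$fnd_sims)
            seqs <- census_gene_sequences(cc, phased$registry, model, g)
            td <- if (length(seqs) >= 4L) tajimas_d(seqs) else NULL
            p_taj <- NA_real_
            d_val <- NA_real_
            if (!is.null(td) && !is.na(td$D)) {
              sims <- coalescent_simulate(models$constant, n = length(seqs),
                                          reps = cfg$tajima_reps)
              td <- tajima_significance(td, sims)
              p_taj <- td$p_two_tail; d_val <- td$D
            }
            rows[[length(rows) + 1L]] <- data.frame(
              locus = locus, gene = g, motif = "All", k = sp$k, F = sp$F,
              F_nd = ew$F_nd, p_slatkin = ew$p_slatkin,
              tajima_D = d_val, p_two_tail = p_taj, stringsAsFactors = FALSE)
          }
        }
        # motif-restricted F_nd on binding-site exclusive sets
        sites <- read_binding_sites()
        cc <- haplotype_census(phased, "HLA")
        for (g in intersect(names(sites), phased$models$HLA$genes)) {
          at <- census_gene_allotypes(cc, phased$registry, phased$models$HLA, g)
          if (is.null(at)) next
          for (motif in names(sites[[g]]$exclusive)) {
            resid <- sites[[g]]$exclusive[[motif]]
            if (!length(resid)) next
            sp <- motif_project(at, resid, label = paste(g, motif))
            ew <- slatkin_fnd(sp, n_sim = cfg$fnd_sims)
            rows[[length(rows) + 1L]] <- data.frame(
              locus = "HLA", gene = g, motif = motif, k = sp$k, F = sp$F,
              F_nd = ew$F_nd, p_slatkin = ew$p_slatkin,
              tajima_D = NA_real_, p_two_tail = NA_real_,
              stringsAsFactors = FALSE)
          }
        }
        sel <- do.call(rbind, rows)
        write.table(format(sel, digits = 6), file.path(cfg$outdir, "selection.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report$selection_rows <<- nrow(sel)
      })
    } else if (st == "diversity") {
      run_stage(st, function() {
        if (is.null(phased)) stop("diversity stage needs phased data; run 'phase'")
        cc <- haplotype_census(phased, "KIR")
        model <- phased$models$KIR
        seqs <- haplotype_concat_sequences(cc, phased$registry, model)
        mm <- mismatch_distribution(seqs)
        write.table(data.frame(p_distance = mm$distances),
                    file.path(cfg$outdir, "mismatch.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        if (length(seqs) >= 2L) {
          net <- hamming_network(seqs, frequencies = cc$freq)
          jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                               file.path(cfg$outdir, "network.json"),
                               dataframe = "rows", digits = NA)
        }
        ms <- marker_series(cc, phased$registry, model)
        if (nrow(ms) >= 15L) {
          prof <- sliding_window_maf(ms)
          write.table(prof, file.path(cfg$outdir, "maf_profile.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
        }
        cum <- list()
        for (resn in c("allele", "allotype")) {
          ccr <- haplotype_census(phased, "KIR", resolution = resn)
          cv <- cumulative_haplotype_curve(ccr)
          cum[[length(cum) + 1L]] <- data.frame(resolution = resn,
                                                rank = seq_along(cv),
                                                cumulative = cv)
        }
        write.table(do.call(rbind, cum), file.path(cfg$outdir, "cumulative.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report$mismatch_pairs <<- length(mm$distances)
      })
    } else if (st == "coevolve") {
      run_stage(st, function() {
        if (is.null(phased)) stop("coevolve stage needs phased data; run 'phase'")
        scan <- coevolution_scan(phased, cfg$scan$hla_genes, cfg$scan$kir_genes,
                                 alpha = cfg$scan$alpha,
                                 n_perm = cfg$scan$n_perm, seed = sseed)
        if (nrow(scan$results))
          write.table(format(scan$results, digits = 6),
                      file.path(cfg$outdir, "scan.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        report$scan_pairs <<- nrow(scan$results)
      })
    } else stop("unknown stage: ", st)
    report$stages <- c(report$stages, st)
  }
  if (!is.null(cfg$genotype_table))
    manifest$input_md5 <- as.list(tools::md5sum(c(cfg$genotype_table, cfg$alleles)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline report> stages run:", paste(x$stages, collapse = " -> "), "\n")
  for (nm in setdiff(names(x), "stages")) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
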