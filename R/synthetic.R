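# one canonical codon per amino acid, for deterministic reverse translation
AA_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
              E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
              M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
              Y = "TAT", V = "GTT")
# a synonymous alternative for a subset of amino acids
AA_CODON_SYN <- c(A = "GCC", R = "CGC", N = "AAC", G = "GGC", L = "CTC",
                  S = "TCC", T = "ACC", V = "GTC")

reverse_translate <- function(protein, synonymous_at = integer(0)) {
  aa <- strsplit(protein, "")[[1]]
  codons <- AA_CODON[aa]
  if (length(synonymous_at)) {
    for (i in synonymous_at) {
      alt <- AA_CODON_SYN[aa[i]]
      if (!is.na(alt)) codons[i] <- alt
    }
  }
  paste(codons, collapse = "")
}

#' Synthetic allele registry
#'
#' Generates an allele registry with the statistical structure the analysis
#' assumes: per gene, a random base protein with a configurable number of
#' polymorphic residues drawn preferentially from the gene's binding-site
#' residues, k allele variants differing at those residues, and optional
#' synonymous variants (same protein, alternative codons). HLA-A/B sequences
#' segregate arginine/glycine at residue 83 (Bw4-positive and -negative
#' allotypes); HLA-C sequences segregate asparagine/lysine at residue 80 (C1
#' versus C2). Sequences are synthetic stand-ins, realistic only at the
#' residues the analysis reads.
#'
#' @param models Locus models (default [default_locus_models()]).
#' @param k_per_gene Named integer vector of allele counts per gene; genes not
#'   named get `k_default`.
#' @param k_default Default alleles per gene.
#' @param n_polymorphic Polymorphic residues per gene.
#' @param syn_per_gene Number of alleles per gene that also get a synonymous
#'   duplicate (exercises allotype collapsing).
#' @param seed Integer seed.
#' @return An `allele_registry`.
#' @export
synthetic_allele_registry <- function(models = default_locus_models(),
                                      k_per_gene = NULL, k_default = 4L,
                                      n_polymorphic = 6L, syn_per_gene = 1L,
                                      seed = 1L) {
  set.seed(seed)
  sites <- read_binding_sites()
  aa_pool <- names(AA_CODON)
  rows <- list()
  for (locus in names(models)) {
    model <- models[[locus]]
    for (g in model$genes) {
      k <- if (!is.null(k_per_gene) && g %in% names(k_per_gene)) k_per_gene[[g]]
           else k_default
      mature_len <- model$aln_len[[g]] / 3L - model$leader_aa[[g]]
      base <- sample(aa_pool, mature_len, replace = TRUE)
      # fix epitope-determining residues on the base
      if (g %in% c("HLA-A", "HLA-B")) base[83] <- "R"
      if (g == "HLA-C") base[80] <- "N"
      # candidate polymorphic residues: the gene's binding-site residues,
      # topped up with random positions
      cand <- unique(unlist(sites[[g]]$sites))
      cand <- cand[cand <= mature_len]
      poly <- unique(c(
        if (g %in% c("HLA-A", "HLA-B")) 83L else integer(0),
        if (g == "HLA-C") 80L else integer(0),
        if (length(cand)) sample(cand, min(length(cand), n_polymorphic)) else integer(0)))
      if (length(poly) < n_polymorphic)
        poly <- unique(c(poly, sample(setdiff(seq_len(mature_len), poly),
                                      n_polymorphic - length(poly))))
      poly <- sort(poly[seq_len(min(length(poly), n_polymorphic))])
      # two residue states per polymorphic position
      alt_state <- vapply(poly, function(r) {
        if (r == 83L && g %in% c("HLA-A", "HLA-B")) return("G")
        if (r == 80L && g == "HLA-C") return("K")
        sample(setdiff(aa_pool, base[r]), 1L)
      }, character(1))
      leader <- c("M", sample(aa_pool, model$leader_aa[[g]] - 1L, replace = TRUE))
      seen_patterns <- character(0)
      if (k > 2^length(poly))
        stop("gene ", g, ": cannot make ", k, " distinct alleles from ",
             length(poly), " polymorphic residues")
      for (a in seq_len(k)) {
        repeat {
          # allele 1 is the base, allele 2 its full complement (so every
          # polymorphic residue segregates); further alleles are random
          use_alt <- if (a == 1L) rep(FALSE, length(poly))
                     else if (a == 2L) rep(TRUE, length(poly))
                     else runif(length(poly)) < 0.5
          pat <- paste(as.integer(use_alt), collapse = "")
          if (!pat %in% seen_patterns) { seen_patterns <- c(seen_patterns, pat); break }
        }
        prot <- base
        prot[poly[use_alt]] <- alt_state[use_alt]
        full <- paste(c(leader, prot), collapse = "")
        name <- if (grepl("^HLA-", g))
          paste0(model$name_prefix[[g]], "*", sprintf("%02d", a), ":01")
        else paste0(g, "*", sprintf("%03d", a), "01")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, name = name, expressed = TRUE,
          cds = reverse_translate(full), stringsAsFactors = FALSE)
        if (a <= syn_per_gene) {
          syn_name <- if (grepl("^HLA-", g))
            paste0(model$name_prefix[[g]], "*", sprintf("%02d", a), ":02")
          else paste0(g, "*", sprintf("%03d", a), "02")
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, name = syn_name, expressed = TRUE,
            cds = reverse_translate(full, synonymous_at = seq(5L, length(leader) + 3L)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  new_allele_registry(do.call(rbind, rows), models)
}

#' Synthetic haplotype pool
#'
#' Builds a pool of distinct haplotypes over one locus by sampling alleles per
#' gene from the registry, with pool frequencies drawn by [sample_spectrum()].
#' For the KIR locus, KIR2DL2 and KIR2DL3 are mutually exclusive
#' (one is ABSENT whenever the other is carried) and non-framework genes are
#' absent with probability `p_absent`.
#'
#' @param registry An `allele_registry`.
#' @param model A `locus_model`.
#' @param n_haplotypes Pool size.
#' @param spectrum_mode `"balanced"`, `"directional"` or `"neutral_coalescent"`.
#' @param p_absent Per-gene absence probability for non-framework genes.
#' @param seed Integer seed.
#' @return List of class `haplotype_pool`: `haplotypes` (list of named
#'   vectors), `freqs`.
#' @export
synthetic_haplotype_pool <- function(registry, model, n_haplotypes = 10L,
                                     spectrum_mode = "balanced", p_absent = 0.2,
                                     seed = 1L) {
  set.seed(seed)
  haps <- list()
  tries <- 0L
  excl <- c("KIR2DL2", "KIR2DL3")
  while (length(haps) < n_haplotypes) {
    if ((tries <- tries + 1L) > 200L * n_haplotypes)
      stop("cannot build ", n_haplotypes, " distinct haplotypes from this registry")
    h <- vapply(model$genes, function(g) {
      alleles <- registry$name[registry$gene == g]
      if (!model$framework[[g]] && !(g %in% excl) && runif(1) < p_absent)
        return(ABSENT)
      sample(alleles, 1L)
    }, character(1))
    if (all(excl %in% model$genes)) {
      keep <- sample(excl, 1L)
      h[setdiff(excl, keep)] <- ABSENT
    }
    key <- hap_key(h)
    if (!key %in% vapply(haps, hap_key, character(1)))
      haps[[length(haps) + 1L]] <- h
  }
  freqs <- sample_spectrum(spectrum_mode, k = n_haplotypes, n = 200L,
                           seed = seed + 1L)
  structure(list(haplotypes = haps, freqs = freqs), class = "haplotype_pool")
}

#' Frequency spectra for haplotype pools
#'
#' `balanced` draws near-even frequencies from a symmetric Dirichlet with
#' concentration 100; `directional` gives one dominant class (frequency
#' 0.86-0.95) with the remainder Dirichlet(1); `neutral_coalescent` draws an
#' allele configuration from the Ewens sampling formula conditional on k (the
#' coalescent infinite-alleles spectrum) for a sample of size n and returns
#' the relative counts.
#'
#' @param mode Spectrum mode.
#' @param k Number of classes (k >= 1).
#' @param n Sample size (used by the coalescent mode).
#' @param seed Integer seed.
#' @return Frequency vector of length k summing to 1.
#' @export
sample_spectrum <- function(mode = c("balanced", "directional", "neutral_coalescent"),
                            k, n = 100L, seed = NULL) {
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) return(1)
  if (mode == "balanced") {
    x <- rgamma(k, shape = 100, rate = 1)
    x / sum(x)
  } else if (mode == "directional") {
    p1 <- runif(1, 0.86, 0.95)
    rest <- rgamma(k - 1L, shape = 1, rate = 1)
    c(p1, (1 - p1) * rest / sum(rest))
  } else {
    cfg <- ewens_config(n, k)
    sort(cfg / sum(cfg), decreasing = TRUE)
  }
}

# one Ewens configuration conditional on k (Chinese restaurant + rejection)
ewens_config <- function(n, k, max_tries = 100000L) {
  if (k >= n) return(rep(1L, n))
  theta <- ewens_theta_for_k(n, k)
  for (try in seq_len(max_tries)) {
    tab <- c(1L)
    for (i in seq_len(n - 1L)) {
      if (runif(1) * (theta + i) < theta) tab <- c(tab, 1L)
      else {
        t <- sample.int(length(tab), 1L, prob = tab)
        tab[t] <- tab[t] + 1L
      }
      if (length(tab) > k) break
    }
    if (length(tab) == k) return(tab)
  }
  stop("Ewens rejection sampling failed for n=", n, ", k=", k)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_cohort()] needs: pools for the KIR-like and
#' HLA-like loci (on different chromosomes, segregating independently), the
#' registry and models they refer to, cohort shape (mother-child pairs plus
#' unrelated individuals), the cen/tel crossover rate per KIR transmission,
#' and an optional planted receptor-ligand coupling (see [plant_coupling()]).
#'
#' @param seed Integer seed; fully determines the simulated cohort.
#' @param n_pairs Number of mother-child pairs.
#' @param n_unrelated Number of additional unrelated individuals.
#' @param kir_pool,hla_pool `haplotype_pool` objects.
#' @param registry,models The allele registry and locus models.
#' @param recomb_rate Probability of a centromeric/telomeric crossover in a
#'   maternal KIR transmission.
#' @param coupling Optional coupling spec (set via [plant_coupling()]).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed, n_pairs, n_unrelated, kir_pool, hla_pool,
                       registry, models = default_locus_models(),
                       recomb_rate = 0, coupling = NULL) {
  for (pool in list(kir_pool, hla_pool)) {
    if (!length(pool$haplotypes)) stop("empty haplotype pool")
    if (abs(sum(pool$freqs) - 1) > 1e-9) stop("pool frequencies not normalized")
  }
  if (!is.null(coupling) &&
      (coupling$strength < 0 || coupling$strength > 1))
    stop("coupling_strength must be in [0, 1]")
  structure(list(seed = seed, n_pairs = n_pairs, n_unrelated = n_unrelated,
                 kir_pool = kir_pool, hla_pool = hla_pool, registry = registry,
                 models = models, recomb_rate = recomb_rate, coupling = coupling),
            class = "sim_config")
}

# residue-set class of one haplotype: the protein substring over `residues`
# of `gene` (absent gene -> gaps)
hap_residue_state <- function(hap, gene, residues, registry) {
  allele <- hap[[gene]]
  if (allele == ABSENT) return(paste(rep("-", length(residues)), collapse = ""))
  prot <- registry$protein[match(allele, registry$name)]
  paste(vapply(residues, function(r) substr(prot, r, r), character(1)), collapse = "")
}

#' Plant receptor-ligand coupling into a simulation config
#'
#' Marks an HLA residue set and a KIR residue set as coupled: during
#' simulation, individuals are rejection-sampled so that the proportion whose
#' HLA and KIR focal-class dosages (0, 1 or 2 copies) agree exceeds the
#' independence expectation, by
#' an amount controlled by `strength` (0 = independence, 1 = complete
#' matching). Coupling acts on whole individuals, not on pool frequencies, so
#' marginal haplotype frequencies are essentially preserved. The focal class
#' on each side is the most frequent residue-set state in the pool; an error
#' is raised if either residue set is monomorphic in its pool (coupling would
#' be undefined).
#'
#' @param cfg A `sim_config`.
#' @param hla_gene,hla_residues Ligand-side gene and mature-numbered residues.
#' @param kir_gene,kir_residues Receptor-side gene and residues.
#' @param strength Coupling strength in \[0, 1\].
#' @return The config with `$coupling` set.
#' @export
plant_coupling <- function(cfg, hla_gene, hla_residues, kir_gene, kir_residues,
                           strength) {
  stopifnot(inherits(cfg, "sim_config"))
  if (strength < 0 || strength > 1) stop("coupling_strength must be in [0, 1]")
  states_h <- vapply(cfg$hla_pool$haplotypes, hap_residue_state, character(1),
                     gene = hla_gene, residues = hla_residues, registry = cfg$registry)
  states_k <- vapply(cfg$kir_pool$haplotypes, hap_residue_state, character(1),
                     gene = kir_gene, residues = kir_residues, registry = cfg$registry)
  for (nm in list(list(s = states_h, lab = "HLA"), list(s = states_k, lab = "KIR"))) {
    if (length(unique(nm$s)) < 2L)
      stop(nm$lab, " coupling residue set is monomorphic in the pool; ",
           "coupling undefined")
  }
  focal_h <- names(sort(tapply(cfg$hla_pool$freqs, states_h, sum), decreasing = TRUE))[1]
  focal_k <- names(sort(tapply(cfg$kir_pool$freqs, states_k, sum), decreasing = TRUE))[1]
  cfg$coupling <- list(hla_gene = hla_gene, hla_residues = hla_residues,
                       kir_gene = kir_gene, kir_residues = kir_residues,
                       strength = strength,
                       focal_h = focal_h, focal_k = focal_k)
  cfg
}

# focal-class dosage (0, 1 or 2 copies) of an individual's genotype at one
# side of a coupling
focal_dosage <- function(h1, h2, gene, residues, registry, focal) {
  s1 <- hap_residue_state(h1, gene, residues, registry)
  s2 <- hap_residue_state(h2, gene, residues, registry)
  (s1 == focal) + (s2 == focal)
}

#' Simulate a cohort with known truth
#'
#' Mothers receive two independent pool haplotypes per locus; each child one
#' maternal haplotype (with an optional cen/tel crossover for KIR) and one
#' paternal haplotype drawn from the pool (fathers are latent, matching a
#' design that samples only mothers and children). Loci segregate
#' independently. When a coupling is planted, unrelated individuals and
#' mothers are rejection-sampled on the agreement of their HLA and KIR
#' focal-class dosages; children inherit whatever association their parents carry.
#'
#' @param cfg A `sim_config`.
#' @return List with `cohort` (a `kir_cohort`) and `truth` (a `truth_set`:
#'   per-individual true haplotype pairs per locus, which haplotype is
#'   maternal, and the coupling spec).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  models <- cfg$models
  kir_model <- models$KIR
  pools <- list(KIR = cfg$kir_pool, HLA = cfg$hla_pool)
  draw <- function(locus) {
    pool <- pools[[locus]]
    pool$haplotypes[[sample.int(length(pool$haplotypes), 1L,
                                prob = pool$freqs)]]
  }
  boundary <- cfg$models$KIR$cen_tel_boundary_after
  cen_genes <- kir_model$genes[seq_len(match(boundary, kir_model$genes))]
  crossover <- function(h1, h2) {
    out <- h1
    tel <- setdiff(kir_model$genes, cen_genes)
    out[tel] <- h2[tel]
    out
  }
  accept_individual <- function(hk1, hk2, hh1, hh2) {
    if (is.null(cfg$coupling)) return(TRUE)
    cp <- cfg$coupling
    mk <- focal_dosage(hk1, hk2, cp$kir_gene, cp$kir_residues, cfg$registry, cp$focal_k)
    mh <- focal_dosage(hh1, hh2, cp$hla_gene, cp$hla_residues, cfg$registry, cp$focal_h)
    if (mk == mh) TRUE else runif(1) >= cp$strength
  }
  draw_individual <- function() {
    repeat {
      hk <- list(draw("KIR"), draw("KIR"))
      hh <- list(draw("HLA"), draw("HLA"))
      if (accept_individual(hk[[1]], hk[[2]], hh[[1]], hh[[2]]))
        return(list(KIR = hk, HLA = hh))
    }
  }
  ids <- character(0); mothers_of <- character(0)
  truth <- list(); genotypes <- list()
  add_individual <- function(id, mother_id, haps, maternal = NA_integer_) {
    geno <- list()
    for (locus in names(models)) {
      for (g in models[[locus]]$genes)
        geno[[g]] <- sort(c(haps[[locus]][[1]][[g]], haps[[locus]][[2]][[g]]))
    }
    genotypes[[id]] <<- geno
    truth[[id]] <<- list(haplotypes = haps, maternal = maternal)
    ids <<- c(ids, id); mothers_of[id] <<- mother_id
  }
  for (p in seq_len(cfg$n_pairs)) {
    mid <- sprintf("M%03d", p); cid <- sprintf("C%03d", p)
    mhaps <- draw_individual()
    # child: maternal transmitted per locus + paternal from pool
    chaps <- list()
    for (locus in names(models)) {
      which_m <- sample.int(2L, 1L)
      transmitted <- mhaps[[locus]][[which_m]]
      if (locus == "KIR" && cfg$recomb_rate > 0 && runif(1) < cfg$recomb_rate) {
        other <- mhaps[[locus]][[3L - which_m]]
        transmitted <- if (runif(1) < 0.5) crossover(transmitted, other)
                       else crossover(other, transmitted)
      }
      chaps[[locus]] <- list(transmitted, draw(locus))
    }
    add_individual(mid, NA_character_, mhaps)
    add_individual(cid, mid, chaps, maternal = 1L)
  }
  for (u in seq_len(cfg$n_unrelated)) {
    add_individual(sprintf("U%03d", u), NA_character_, draw_individual())
  }
  cohort <- new_cohort(ids, mothers_of, genotypes, cfg$registry, models,
                       provenance = list(simulated = TRUE, seed = cfg$seed))
  truth_set <- structure(list(individuals = truth, coupling = cfg$coupling,
                              config = cfg),
                         class = "truth_set")
  list(cohort = cohort, truth = truth_set)
}

#' Write a simulated cohort with its truth files
#'
#' Emits the genotype TSV and registry FASTA plus `truth_haplotypes.tsv`,
#' `truth_pairs.tsv` (when epitope configuration applies) and a JSON manifest
#' describing the generator settings. Generator choices are stand-ins for an
#' undocumented real-world sampling process and are labelled as such in the
#' manifest.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param pair_counts Optional logical: also write per-individual true
#'   functional pair counts (requires HLA/KIR epitope config to apply to the
#'   registry).
#' @return `dir`, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir, pair_counts = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(sim$cohort, file.path(dir, "genotypes.tsv"),
               file.path(dir, "alleles.fasta"))
  rows <- list()
  for (id in names(sim$truth$individuals)) {
    tr <- sim$truth$individuals[[id]]
    for (locus in names(tr$haplotypes)) {
      for (h in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, locus = locus, hap_index = h,
          haplotype = hap_key(tr$haplotypes[[locus]][[h]]),
          maternal = !is.na(tr$maternal[1]) && tr$maternal[1] == h,
          stringsAsFactors = FALSE)
      }
    }
  }
  write.table(do.call(rbind, rows), file.path(dir, "truth_haplotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (pair_counts) {
    epi <- assign_epitopes_registry(sim$cohort$registry)
    counts <- cohort_pair_distribution(sim$cohort, epitopes = epi)$counts
    write.table(data.frame(individual_id = names(counts), pairs = counts),
                file.path(dir, "truth_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- sim$truth$config
  manifest <- list(
    generator = "kirhla synthetic cohort (stand-in for an undeposited study design)",
    seed = cfg$seed, n_pairs = cfg$n_pairs, n_unrelated = cfg$n_unrelated,
    recomb_rate = cfg$recomb_rate,
    kir_pool_size = length(cfg$kir_pool$haplotypes),
    hla_pool_size = length(cfg$hla_pool$haplotypes),
    coupling = if (is.null(cfg$coupling)) NULL else
      cfg$coupling[c("hla_gene", "hla_residues", "kir_gene", "kir_residues",
                     "strength")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' The one-pair worked example cohort
#'
#' A single individual homozygous for common ligand and receptor haplotypes:
#' HLA A*23:01, B*44:03, C*04:01; KIR2DL2*001 with no KIR2DL1/S1/S2 and the
#' non-expressed KIR3DL1*004. Under the shipped interaction table this
#' genotype forms exactly one viable receptor-ligand allotype pair,
#' KIR2DL2*001 : C*04:01. The registry sequences are synthetic stand-ins for
#' the named allotypes, correct at the epitope-determining residues
#' (arginine 83 for Bw4; residue 80 for C1/C2); it also carries B*53:01 and
#' B*35:01 - allotypes identical except across the Bw4 motif - and an
#' expressed KIR3DL1*001 for constructing related examples.
#'
#' @return A `kir_cohort` with one individual `"GA001"`.
#' @export
worked_example_cohort <- function() {
  models <- default_locus_models()
  hla_m <- models$HLA; kir_m <- models$KIR
  mk_prot <- function(model, gene, fix = list()) {
    mature_len <- model$aln_len[[gene]] / 3L - model$leader_aa[[gene]]
    prot <- rep("A", mature_len)
    prot[1] <- "G"
    for (r in names(fix)) prot[as.integer(r)] <- fix[[r]]
    leader <- c("M", rep("L", model$leader_aa[[gene]] - 1L))
    paste(c(leader, prot), collapse = "")
  }
  # Bw4-positive window ends in R83; Bw4-negative differs across 77-83 only
  bw4_fix <- list(`77` = "N", `78` = "L", `79` = "R", `80` = "I", `81` = "A",
                  `82` = "L", `83` = "R")
  bw6_fix <- list(`77` = "S", `78` = "L", `79` = "R", `80` = "N", `81` = "L",
                  `82` = "R", `83` = "G")
  rows <- rbind(
    data.frame(gene = "HLA-A", name = "A*23:01", expressed = TRUE,
               cds = reverse_translate(mk_prot(hla_m, "HLA-A", bw4_fix))),
    data.frame(gene = "HLA-B", name = "B*44:03", expressed = TRUE,
               cds = reverse_translate(mk_prot(hla_m, "HLA-B", bw4_fix))),
    data.frame(gene = "HLA-B", name = "B*53:01", expressed = TRUE,
               cds = reverse_translate(mk_prot(hla_m, "HLA-B", c(bw4_fix, list(`2` = "C"))))),
    data.frame(gene = "HLA-B", name = "B*35:01", expressed = TRUE,
               cds = reverse_translate(mk_prot(hla_m, "HLA-B", c(bw6_fix, list(`2` = "C"))))),
    data.frame(gene = "HLA-C", name = "C*04:01", expressed = TRUE,
               cds = reverse_translate(mk_prot(hla_m, "HLA-C", list(`80` = "K")))),
    data.frame(gene = "HLA-C", name = "C*07:01", expressed = TRUE,
               cds = reverse_translate(mk_prot(hla_m, "HLA-C", list(`80` = "N")))),
    data.frame(gene = "KIR3DL3", name = "KIR3DL3*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR3DL3"))),
    data.frame(gene = "KIR2DL2", name = "KIR2DL2*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR2DL2"))),
    data.frame(gene = "KIR2DL3", name = "KIR2DL3*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR2DL3"))),
    data.frame(gene = "KIR2DL1", name = "KIR2DL1*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR2DL1"))),
    data.frame(gene = "KIR2DL4", name = "KIR2DL4*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR2DL4"))),
    data.frame(gene = "KIR3DL1", name = "KIR3DL1*004", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR3DL1", list(`86` = "L")))),
    data.frame(gene = "KIR3DL1", name = "KIR3DL1*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR3DL1", list(`86` = "S")))),
    data.frame(gene = "KIR3DL2", name = "KIR3DL2*001", expressed = TRUE,
               cds = reverse_translate(mk_prot(kir_m, "KIR3DL2"))))
  registry <- new_allele_registry(rows, models)
  geno <- list(
    "HLA-A" = c("A*23:01", "A*23:01"),
    "HLA-B" = c("B*44:03", "B*44:03"),
    "HLA-C" = c("C*04:01", "C*04:01"),
    "KIR3DL3" = c("KIR3DL3*001", "KIR3DL3*001"),
    "KIR2DL2" = c("KIR2DL2*001", "KIR2DL2*001"),
    "KIR2DL3" = c(ABSENT, ABSENT),
    "KIR2DL1" = c(ABSENT, ABSENT),
    "KIR2DL4" = c("KIR2DL4*001", "KIR2DL4*001"),
    "KIR3DL1" = c("KIR3DL1*004", "KIR3DL1*004"),
    "KIR3DL2" = c("KIR3DL2*001", "KIR3DL2*001"))
  new_cohort("GA001", c(GA001 = NA_character_), list(GA001 = geno),
             registry, models)
}

#' Purpose-built configuration for the receptor-ligand coupling study
#'
#' Constructs a registry and haplotype pools designed so that the coupled
#' residue sets form clean linkage groups: HLA-B segregates two classes at
#' residues 77 and 83 (the Bw4 window, in perfect LD with each other and
#' independent of a third polymorphic HLA-B residue), and KIR3DL1 segregates
#' two classes at residues 31, 44 and 86 (in perfect LD), independent of the
#' other polymorphic KIR residues. Pools enumerate all combinations at
#' near-balanced frequencies, so every other residue pair is unlinked. The
#' returned config plants the HLA-B \{77,83\} - KIR3DL1 \{31,44,86\} coupling
#' at the requested strength over `n_unrelated` unrelated individuals.
#'
#' @param seed Integer seed.
#' @param n_unrelated Cohort size (unrelated individuals).
#' @param strength Coupling strength in \[0,1\] (0 = independence).
#' @return A `sim_config` with coupling planted (unless `strength` is NULL).
#' @export
coupling_study_config <- function(seed, n_unrelated = 200L, strength = 0.5) {
  models <- default_locus_models()
  hla_m <- models$HLA; kir_m <- models$KIR
  mk_prot <- function(model, gene, fix = list()) {
    mature_len <- model$aln_len[[gene]] / 3L - model$leader_aa[[gene]]
    prot <- rep("A", mature_len)
    for (r in names(fix)) prot[as.integer(r)] <- fix[[r]]
    paste(c("M", rep("L", model$leader_aa[[gene]] - 1L), prot), collapse = "")
  }
  row <- function(gene, name, fix = list(), model = kir_m) {
    data.frame(gene = gene, name = name, expressed = TRUE,
               cds = reverse_translate(mk_prot(model, gene, fix)),
               stringsAsFactors = FALSE)
  }
  bw4 <- list(`77` = "N", `83` = "R"); bw6 <- list(`77` = "S", `83` = "G")
  k3dl1_hi <- list(`31` = "I", `44` = "R", `86` = "S")
  k3dl1_lo <- list(`31` = "T", `44` = "K", `86` = "L")
  rows <- rbind(
    row("HLA-A", "A*01:01", list(`62` = "G"), hla_m),
    row("HLA-A", "A*02:01", list(`62` = "W"), hla_m),
    row("HLA-B", "B*01:01", c(bw4, list(`116` = "Y")), hla_m),
    row("HLA-B", "B*02:01", c(bw4, list(`116` = "F")), hla_m),
    row("HLA-B", "B*03:01", c(bw6, list(`116` = "Y")), hla_m),
    row("HLA-B", "B*04:01", c(bw6, list(`116` = "F")), hla_m),
    row("HLA-C", "C*01:01", list(`80` = "N", `49` = "C"), hla_m),
    row("HLA-C", "C*02:01", list(`80` = "K", `49` = "R"), hla_m),
    row("KIR3DL3", "KIR3DL3*001", list(`10` = "D")),
    row("KIR3DL3", "KIR3DL3*002", list(`10` = "E")),
    row("KIR2DL2", "KIR2DL2*001"),
    row("KIR2DL3", "KIR2DL3*001"),
    row("KIR2DL1", "KIR2DL1*001", list(`154` = "P")),
    row("KIR2DL1", "KIR2DL1*002", list(`154` = "S")),
    row("KIR2DL4", "KIR2DL4*001"),
    row("KIR3DL1", "KIR3DL1*001", c(k3dl1_hi, list(`140` = "G"))),
    row("KIR3DL1", "KIR3DL1*002", c(k3dl1_hi, list(`140` = "V"))),
    row("KIR3DL1", "KIR3DL1*005", c(k3dl1_lo, list(`140` = "G"))),
    row("KIR3DL1", "KIR3DL1*006", c(k3dl1_lo, list(`140` = "V"))),
    row("KIR3DL2", "KIR3DL2*001", list(`20` = "H")),
    row("KIR3DL2", "KIR3DL2*002", list(`20` = "Q")))
  registry <- new_allele_registry(rows, models)
  set.seed(seed)
  # HLA pool: every combination of the per-gene alleles
  hla_combos <- expand.grid(a = c("A*01:01", "A*02:01"),
                            b = c("B*01:01", "B*02:01", "B*03:01", "B*04:01"),
                            c = c("C*01:01", "C*02:01"),
                            stringsAsFactors = FALSE)
  hla_haps <- lapply(seq_len(nrow(hla_combos)), function(i)
    setNames(c(hla_combos$a[i], hla_combos$b[i], hla_combos$c[i]), hla_m$genes))
  kir_combos <- expand.grid(g1 = c("KIR3DL3*001", "KIR3DL3*002"),
                            g4 = c("KIR2DL1*001", "KIR2DL1*002"),
                            g6 = c("KIR3DL1*001", "KIR3DL1*002",
                                   "KIR3DL1*005", "KIR3DL1*006"),
                            g7 = c("KIR3DL2*001", "KIR3DL2*002"),
                            d2 = c(TRUE, FALSE), stringsAsFactors = FALSE)
  kir_haps <- lapply(seq_len(nrow(kir_combos)), function(i) {
    setNames(c(kir_combos$g1[i],
               if (kir_combos$d2[i]) c("KIR2DL2*001", ABSENT)
               else c(ABSENT, "KIR2DL3*001"),
               kir_combos$g4[i], "KIR2DL4*001", kir_combos$g6[i],
               kir_combos$g7[i]), kir_m$genes)
  })
  mk_pool <- function(haps, s) {
    structure(list(haplotypes = haps,
                   freqs = sample_spectrum("balanced", k = length(haps), seed = s)),
              class = "haplotype_pool")
  }
  cfg <- sim_config(seed = seed, n_pairs = 0L, n_unrelated = n_unrelated,
                    kir_pool = mk_pool(kir_haps, seed + 1L),
                    hla_pool = mk_pool(hla_haps, seed + 2L),
                    registry = registry, models = models)
  if (!is.null(strength) && strength > 0)
    cfg <- plant_coupling(cfg, "HLA-B", c(77L, 83L), "KIR3DL1", c(31L, 44L, 86L),
                          strength = strength)
  cfg
}

#' Phased cohort from simulation truth
#'
#' Wraps a simulated cohort with its true haplotype phases, producing the
#' `phased_cohort` the downstream residue-genotype analyses consume without
#' running the phaser. Used to test stages in isolation from phasing quality,
#' and by the truth-consistency checks.
#'
#' @param sim Result of [simulate_cohort()].
#' @return A `phased_cohort` with resolution `"truth"` everywhere.
#' @export
phased_from_truth <- function(sim) {
  cohort <- sim$cohort
  phased <- list()
  for (locus in names(cohort$models)) {
    res <- list()
    for (id in cohort$individuals$id) {
      tr <- sim$truth$individuals[[id]]
      h1 <- tr$haplotypes[[locus]][[1]]
      h2 <- tr$haplotypes[[locus]][[2]]
      if (hap_key(h2) < hap_key(h1)) { tmp <- h1; h1 <- h2; h2 <- tmp }
      res[[id]] <- list(h1 = h1, h2 = h2, resolution = "truth",
                        maternal = NA_integer_)
    }
    phased[[locus]] <- res
  }
  cohort$phased <- phased
  class(cohort) <- c("phased_cohort", class(cohort))
  cohort
}
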