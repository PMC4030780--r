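#' Configuration for the synthetic trio-cohort generator
#'
#' The defaults emulate the structure of a 30-proband prenatal trio study:
#' 26 trios and two quads (one of them a monozygotic twin pair), coding de
#' novo events at an expected 1.1 per proband of which 29% are synonymous,
#' rare (<1%) inherited homozygous / compound-heterozygous / X-linked
#' configurations, allele-depth noise including designated mosaic events,
#' and independent per-caller call dropout across three callers.
#'
#' @param n_trios Number of single-proband families.
#' @param n_quads Number of families with two affected probands.
#' @param n_mz_twin_pairs How many of the quads are monozygotic twin pairs
#'   (the twins share one genome, including de novo events).
#' @param n_sites Number of background variant sites segregating in the
#'   population (drawn under Hardy-Weinberg at each site's allele frequency).
#' @param de_novo_rate_per_proband Poisson mean of coding de novo events per
#'   proband genome.
#' @param synonymous_fraction_de_novo Probability that a de novo coding event
#'   is synonymous.
#' @param n_comphet_genes_per_proband,n_homozygous_per_proband,n_hemizygous_per_male_proband
#'   Poisson means of injected inherited candidate-gene events per proband
#'   genome (hemizygous only in males).
#' @param af_distribution Population allele-frequency model for background
#'   sites: a mixture of a log-uniform rare component on
#'   `[rare_min, rare_max]` (weight `rare_weight`) and a Beta(`shape1`,
#'   `shape2`) common component.
#' @param depth_model Sequencing depth model: negative binomial with mean
#'   `mean` and size `size`.
#' @param mosaic_fraction Alternate-allele fraction of designated mosaic de
#'   novo events.
#' @param n_mosaic_events Number of de novo events (cohort-wide) designated
#'   mosaic.
#' @param caller_dropout Per-caller, per-record probability that a caller
#'   misses a call.
#' @param genotype_error Per-individual, per-site probability of a genotype
#'   miscall (het dropped to hom-ref, hom-ref raised to het, hom-alt to het).
#' @param error_rate Per-base sequencing error rate used for allele-depth
#'   noise at homozygous genotypes.
#' @param caller_discordance Probability that a single caller reports an
#'   inflated genotype (het as hom-alt) at a carried site.
#' @param n_genes,gene_length_meanlog,gene_length_sdlog Synthetic gene-model
#'   size and log-normal coding-length parameters.
#' @param diagnostic_fraction Fraction of probands whose first de novo gene
#'   receives a fully supportive evidence record (emulates a diagnosable
#'   case).
#' @param par Pseudoautosomal boundaries, see [par_boundaries_grch37()].
#' @param noiseless If `TRUE`, all noise channels are off: fixed depth, exact
#'   allele splits, GQ 99, no dropout, no genotype error, no caller
#'   discordance. Used for truth-recovery testing.
#' @param seed Integer seed; a fixed seed yields a byte-identical bundle.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 26, n_quads = 2,
                       n_mz_twin_pairs = min(1L, n_quads),
                       n_sites = 400,
                       de_novo_rate_per_proband = 1.1,
                       synonymous_fraction_de_novo = 0.29,
                       n_comphet_genes_per_proband = 3,
                       n_homozygous_per_proband = 1,
                       n_hemizygous_per_male_proband = 1,
                       af_distribution = list(rare_weight = 0.3,
                                              rare_min = 1e-4, rare_max = 0.01,
                                              shape1 = 1.2, shape2 = 4),
                       depth_model = list(mean = 103, size = 8),
                       mosaic_fraction = 0.2,
                       n_mosaic_events = 2,
                       caller_dropout = 0.05,
                       genotype_error = 0.002,
                       error_rate = 0.002,
                       caller_discordance = 0.01,
                       n_genes = 1000,
                       gene_length_meanlog = log(1500),
                       gene_length_sdlog = 0.6,
                       diagnostic_fraction = 0.1,
                       par = par_boundaries_grch37(),
                       noiseless = FALSE,
                       seed = 1L) {
  if (noiseless) {
    caller_dropout <- 0; genotype_error <- 0; error_rate <- 0
    caller_discordance <- 0
  }
  cfg <- list(n_trios = n_trios, n_quads = n_quads,
              n_mz_twin_pairs = n_mz_twin_pairs, n_sites = n_sites,
              de_novo_rate_per_proband = de_novo_rate_per_proband,
              synonymous_fraction_de_novo = synonymous_fraction_de_novo,
              n_comphet_genes_per_proband = n_comphet_genes_per_proband,
              n_homozygous_per_proband = n_homozygous_per_proband,
              n_hemizygous_per_male_proband = n_hemizygous_per_male_proband,
              af_distribution = af_distribution, depth_model = depth_model,
              mosaic_fraction = mosaic_fraction,
              n_mosaic_events = n_mosaic_events,
              caller_dropout = caller_dropout,
              genotype_error = genotype_error, error_rate = error_rate,
              caller_discordance = caller_discordance,
              n_genes = n_genes, gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              diagnostic_fraction = diagnostic_fraction,
              par = par, noiseless = noiseless, seed = as.integer(seed))
  probs <- c(synonymous_fraction_de_novo, caller_dropout, genotype_error,
             error_rate, caller_discordance, diagnostic_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_trios, n_quads, n_mz_twin_pairs, n_sites, n_genes,
              n_mosaic_events)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_mz_twin_pairs > n_quads) stop("n_mz_twin_pairs cannot exceed n_quads")
  if (!is.null(mosaic_fraction) &&
      (mosaic_fraction <= 0 || mosaic_fraction >= 1)) {
    stop("mosaic_fraction must lie in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Synthetic gene model
#'
#' Genes laid out over chromosomes 1-22 and X with log-normal coding lengths
#' (default median 1.5 kb). A slice of the X genes is placed inside PAR1 so
#' pseudoautosomal logic is exercised. About 5% of genes are non-coding
#' (biotype `lincRNA`), which matters only to the CNV gene-overlap filter.
#'
#' @param n_genes Number of genes.
#' @param meanlog,sdlog Log-normal parameters for coding length in bp.
#' @param par PAR boundaries.
#' @return Data frame `gene`, `chrom`, `start`, `end`, `biotype`.
#' @export
synthetic_gene_model <- function(n_genes = 1000, meanlog = log(1500),
                                 sdlog = 0.6, par = par_boundaries_grch37()) {
  chroms <- c(as.character(1:22), "X")
  # X gets ~5% of genes; autosomes share the rest
  w <- c(rep(0.95 / 22, 22), 0.05)
  chrom <- sample(chroms, n_genes, replace = TRUE, prob = w)
  len <- pmax(200L, as.integer(round(exp(rnorm(n_genes, meanlog, sdlog)))))
  start <- integer(n_genes)
  for (ch in chroms) {
    i <- which(chrom == ch)
    if (length(i) == 0) next
    gaps <- as.integer(round(runif(length(i), 5e4, 2e5)))
    base <- if (ch == "X") 3e6 else 1e6  # X genes start beyond PAR1 ...
    start[i] <- as.integer(base + cumsum(gaps) + cumsum(c(0L, head(len[i], -1))))
  }
  # ... except a couple relocated into PAR1 to exercise the boundary
  xi <- which(chrom == "X")
  n_par <- min(2L, length(xi))
  if (n_par > 0) {
    sel <- xi[seq_len(n_par)]
    start[sel] <- as.integer(par$par1[1] + 1e4 + (seq_len(n_par) - 1L) * 5e5)
  }
  biotype <- ifelse(runif(n_genes) < 0.05, "lincRNA", "protein_coding")
  data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
             chrom = chrom, start = start, end = start + len - 1L,
             biotype = biotype, stringsAsFactors = FALSE)
}

.bg_csq_weights <- c(non_synonymous = 0.45, synonymous = 0.35, other = 0.12,
                     stop_gained = 0.03, frameshift_coding = 0.03,
                     essential_splice_site = 0.01, stop_lost = 0.01)
.dn_functional_weights <- c(non_synonymous = 0.87, stop_gained = 0.1,
                            essential_splice_site = 0.03)

.sample_alleles <- function(n, consequence) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  # frameshift events are represented as 1-bp anchored deletions
  fs <- consequence == "frameshift_coding"
  if (any(fs)) {
    ref[fs] <- paste0(ref[fs], sample(bases, sum(fs), replace = TRUE))
    alt[fs] <- substr(ref[fs], 1, 1)
  }
  list(ref = ref, alt = unname(alt))
}

.draw_af <- function(n, afd) {
  rare <- runif(n) < afd$rare_weight
  af <- numeric(n)
  af[rare] <- exp(runif(sum(rare), log(afd$rare_min), log(afd$rare_max)))
  af[!rare] <- rbeta(sum(!rare), afd$shape1, afd$shape2)
  pmin(af, 0.5)
}

# leaf terms of the packaged synthetic phenotype ontology
.sim_hpo_leaves <- function() {
  obo <- system.file("extdata", "hpo_synthetic_subset.obo",
                     package = "triotriage")
  ont <- read_obo(obo)
  all_parents <- unique(unlist(ont$parents))
  setdiff(ont$terms, c(all_parents, ont$roots))
}

#' Simulate a synthetic trio cohort with known truth
#'
#' Generates pedigree, per-individual per-caller call sets, a CNV call table
#' with a common-CNV catalog, phenotypes, a gene-evidence table and a truth
#' table of every injected event. Parental genotypes at background sites are
#' drawn under Hardy-Weinberg at the site's allele frequency and children
#' receive Mendelian transmissions; chrX non-PAR sites are hemizygous in
#' males; monozygotic twins share one genome including de novo events.
#'
#' @param config A [sim_config()].
#' @return A list of class `trio_simulation` with elements `config`,
#'   `cohort`, `gene_model`, `sites`, `calls` (long data frame over
#'   individual x caller x site), `truth`, `cnv` (list `calls`,
#'   `common_catalog`, `truth`), `phenotypes`, `evidence`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gm <- synthetic_gene_model(config$n_genes, config$gene_length_meanlog,
                             config$gene_length_sdlog, config$par)
  coding <- gm[gm$biotype == "protein_coding", , drop = FALSE]
  x_nonpar_genes <- coding[coding$chrom == "X" &
                             is_x_nonpar("X", coding$start, config$par), , drop = FALSE]
  aut_genes <- coding[coding$chrom != "X", , drop = FALSE]
  if (nrow(aut_genes) < 10 || (config$n_hemizygous_per_male_proband > 0 &&
                               nrow(x_nonpar_genes) < 2)) {
    stop("gene model too small for the requested injections")
  }

  ped <- .sim_pedigree(config)
  cohort <- ped$cohort
  genomes <- ped$genomes  # list: probands (1 or 2 ids), family, sex

  # ---- background sites ----------------------------------------------------
  n_bg <- config$n_sites
  sites <- NULL
  if (n_bg > 0) {
    g <- gm[sample(nrow(gm), n_bg, replace = TRUE, prob = gm$end - gm$start + 1), ]
    csq <- sample(names(.bg_csq_weights), n_bg, replace = TRUE,
                  prob = .bg_csq_weights)
    al <- .sample_alleles(n_bg, csq)
    sites <- data.frame(chrom = g$chrom,
                        pos = g$start + as.integer(floor(runif(n_bg) * (g$end - g$start))),
                        ref = al$ref, alt = al$alt, gene = g$gene,
                        consequence = csq,
                        population_af = .draw_af(n_bg, config$af_distribution),
                        origin = "background", stringsAsFactors = FALSE)
  }

  # ---- injected events per genome -----------------------------------------
  inj <- list()   # site rows
  truth <- list() # truth rows
  geno_override <- list() # list of (individual, site_key, count, haploid)
  add_site <- function(gene_row, consequence, af) {
    pos <- gene_row$start + as.integer(floor(runif(1) * (gene_row$end - gene_row$start)))
    al <- .sample_alleles(1, consequence)
    data.frame(chrom = gene_row$chrom, pos = pos, ref = al$ref, alt = al$alt,
               gene = gene_row$gene, consequence = consequence,
               population_af = af, origin = "injected",
               stringsAsFactors = FALSE)
  }
  dn_csq <- function(n) {
    syn <- runif(n) < config$synonymous_fraction_de_novo
    out <- character(n)
    out[syn] <- "synonymous"
    out[!syn] <- sample(names(.dn_functional_weights), sum(!syn),
                        replace = TRUE, prob = .dn_functional_weights)
    out
  }

  for (gi in seq_along(genomes)) {
    gme <- genomes[[gi]]
    used_genes <- character(0)
    fam <- cohort$members[cohort$members$family_id == gme$family, ]
    mother <- fam$individual_id[fam$role == "mother"]
    father <- fam$individual_id[fam$role == "father"]
    kids <- gme$probands
    male <- gme$sex == "male"

    pick_gene <- function(pool) {
      avail <- pool[!(pool$gene %in% used_genes), , drop = FALSE]
      if (nrow(avail) == 0) stop("gene model exhausted by injections")
      row <- avail[sample(nrow(avail), 1), , drop = FALSE]
      used_genes <<- c(used_genes, row$gene)
      row
    }

    # de novo (shared by MZ twins: one draw per genome)
    n_dn <- rpois(1, config$de_novo_rate_per_proband)
    for (k in seq_len(n_dn)) {
      csq <- dn_csq(1)
      pool <- if (male) aut_genes else coding
      grow <- pick_gene(pool)
      s <- add_site(grow, csq, NA_real_)
      inj[[length(inj) + 1]] <- s
      key <- paste(s$chrom, s$pos, s$ref, s$alt, sep = "\r")
      for (kid in kids) {
        geno_override[[length(geno_override) + 1]] <-
          list(ind = kid, key = key, count = 1L)
        truth[[length(truth) + 1]] <- data.frame(
          proband_id = kid, chrom = s$chrom, pos = s$pos, ref = s$ref,
          alt = s$alt, gene = s$gene, consequence = s$consequence,
          class = "de_novo", stringsAsFactors = FALSE)
      }
    }

    # compound-het gene pairs: one maternal + one paternal variant
    n_ch <- rpois(1, config$n_comphet_genes_per_proband)
    for (k in seq_len(n_ch)) {
      grow <- pick_gene(aut_genes)
      for (side in c("a", "b")) {
        csq <- sample(functional_consequences(), 1,
                      prob = c(0.05, 0.08, 0.05, 0.8, 0.02))
        s <- add_site(grow, csq, runif(1, 1e-4, 0.009))
        inj[[length(inj) + 1]] <- s
        key <- paste(s$chrom, s$pos, s$ref, s$alt, sep = "\r")
        carrier <- if (side == "a") mother else father
        geno_override[[length(geno_override) + 1]] <-
          list(ind = carrier, key = key, count = 1L)
        for (kid in kids) {
          geno_override[[length(geno_override) + 1]] <-
            list(ind = kid, key = key, count = 1L)
          truth[[length(truth) + 1]] <- data.frame(
            proband_id = kid, chrom = s$chrom, pos = s$pos, ref = s$ref,
            alt = s$alt, gene = s$gene, consequence = s$consequence,
            class = paste0("comphet_partner_", side), stringsAsFactors = FALSE)
        }
      }
    }

    # homozygous recessive: both parents het, child hom-alt
    n_hom <- rpois(1, config$n_homozygous_per_proband)
    for (k in seq_len(n_hom)) {
      grow <- pick_gene(aut_genes)
      csq <- sample(functional_consequences(), 1,
                    prob = c(0.05, 0.08, 0.05, 0.8, 0.02))
      s <- add_site(grow, csq, runif(1, 1e-4, 0.009))
      inj[[length(inj) + 1]] <- s
      key <- paste(s$chrom, s$pos, s$ref, s$alt, sep = "\r")
      for (p in c(mother, father)) {
        geno_override[[length(geno_override) + 1]] <-
          list(ind = p, key = key, count = 1L)
      }
      for (kid in kids) {
        geno_override[[length(geno_override) + 1]] <-
          list(ind = kid, key = key, count = 2L)
        truth[[length(truth) + 1]] <- data.frame(
          proband_id = kid, chrom = s$chrom, pos = s$pos, ref = s$ref,
          alt = s$alt, gene = s$gene, consequence = s$consequence,
          class = "homozygous", stringsAsFactors = FALSE)
      }
    }

    # X-linked hemizygous: male child, carrier mother, non-carrier father
    if (male && nrow(x_nonpar_genes) > 0) {
      n_hemi <- rpois(1, config$n_hemizygous_per_male_proband)
      for (k in seq_len(n_hemi)) {
        avail <- x_nonpar_genes[!(x_nonpar_genes$gene %in% used_genes), , drop = FALSE]
        if (nrow(avail) == 0) break
        grow <- avail[sample(nrow(avail), 1), , drop = FALSE]
        used_genes <- c(used_genes, grow$gene)
        csq <- sample(functional_consequences(), 1,
                      prob = c(0.05, 0.08, 0.05, 0.8, 0.02))
        s <- add_site(grow, csq, runif(1, 1e-4, 0.009))
        inj[[length(inj) + 1]] <- s
        key <- paste(s$chrom, s$pos, s$ref, s$alt, sep = "\r")
        geno_override[[length(geno_override) + 1]] <-
          list(ind = mother, key = key, count = 1L)
        for (kid in kids) {
          geno_override[[length(geno_override) + 1]] <-
            list(ind = kid, key = key, count = 1L)
          truth[[length(truth) + 1]] <- data.frame(
            proband_id = kid, chrom = s$chrom, pos = s$pos, ref = s$ref,
            alt = s$alt, gene = s$gene, consequence = s$consequence,
            class = "hemizygous", stringsAsFactors = FALSE)
        }
      }
    }
  }

  inj_df <- if (length(inj) > 0) do.call(rbind, inj) else NULL
  sites <- rbind(sites, inj_df)
  # drop accidental duplicate loci (possible but vanishingly rare)
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = "\r")
  keep <- !duplicated(key)
  sites <- sites[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = "\r")
  S <- nrow(sites)

  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(proband_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               gene = character(0), consequence = character(0),
               class = character(0), stringsAsFactors = FALSE)

  # designate mosaic de novo events
  truth$class <- as.character(truth$class)
  dn_idx <- which(truth$class == "de_novo")
  mosaic_keys <- character(0)
  if (config$n_mosaic_events > 0 && length(dn_idx) > 0) {
    # pick events not shared by twins to keep bookkeeping simple
    shared <- truth$pos[dn_idx] %in% truth$pos[dn_idx][duplicated(truth$pos[dn_idx])]
    pick_from <- dn_idx[!shared]
    take <- head(pick_from[sample.int(length(pick_from))], config$n_mosaic_events)
    truth$class[take] <- "mosaic_de_novo"
    mosaic_keys <- paste(truth$proband_id[take], truth$chrom[take],
                         truth$pos[take], truth$ref[take], truth$alt[take],
                         sep = "\r")
  }

  # ---- true genotypes (allele counts) -------------------------------------
  members <- cohort$members
  N <- nrow(members)
  ind_ids <- members$individual_id
  male_ind <- members$sex == "male"
  xnp <- is_x_nonpar(sites$chrom, sites$pos, config$par)
  haploid <- outer(xnp, male_ind, function(x, m) x & m)
  counts <- matrix(0L, nrow = S, ncol = N, dimnames = list(NULL, ind_ids))

  bg <- sites$origin == "background"
  af <- sites$population_af
  fams <- split(seq_len(N), members$family_id)
  for (fi in fams) {
    fm <- members[fi, ]
    mi <- fi[fm$role == "mother"]; pi <- fi[fm$role == "father"]
    if (any(bg)) {
      afb <- af[bg]; xb <- xnp[bg]; nb <- sum(bg)
      m1 <- rbinom(nb, 1, afb); m2 <- rbinom(nb, 1, afb)
      f1 <- rbinom(nb, 1, afb); f2 <- rbinom(nb, 1, afb)
      counts[bg, mi] <- m1 + m2
      counts[bg, pi] <- ifelse(xb, f1, f1 + f2)
    }
    kids <- fi[fm$role == "proband"]
    done_twin <- character(0)
    for (ki in kids) {
      kid_id <- members$individual_id[ki]
      twin <- members$mz_twin_of[ki]
      if (!is.na(twin) && twin %in% done_twin) {
        counts[, ki] <- counts[, match(twin, ind_ids)]
        next
      }
      if (any(bg)) {
        tm <- ifelse(m1 + m2 == 2, 1L, ifelse(m1 + m2 == 0, 0L, rbinom(nb, 1, 0.5)))
        if (members$sex[ki] == "male") {
          tf <- ifelse(xb, 0L, ifelse(f1 + f2 == 2, 1L,
                                      ifelse(f1 + f2 == 0, 0L, rbinom(nb, 1, 0.5))))
        } else {
          tf <- ifelse(xb, f1, ifelse(f1 + f2 == 2, 1L,
                                      ifelse(f1 + f2 == 0, 0L, rbinom(nb, 1, 0.5))))
        }
        counts[bg, ki] <- tm + tf
      }
      done_twin <- c(done_twin, kid_id)
    }
  }
  for (ov in geno_override) {
    si <- match(ov$key, site_key)
    if (!is.na(si)) counts[si, ov$ind] <- ov$count
  }

  # Background-derived candidate configurations are part of the truth:
  # Hardy-Weinberg draws occasionally produce genuine rare functional
  # homozygous / hemizygous / compound-het configurations in a proband,
  # which the screens must report. They are recorded here (at the screens'
  # default 1% rarity rule) so that truth-recovery comparisons are exact.
  func_site <- sites$consequence %in% functional_consequences()
  rare_site <- (is.na(af) | af < 0.01) & func_site
  extra <- list()
  for (gme in genomes) {
    fam <- members[members$family_id == gme$family, ]
    mo <- fam$individual_id[fam$role == "mother"]
    fa <- fam$individual_id[fam$role == "father"]
    m <- counts[, mo]; f <- counts[, fa]
    fhap <- haploid[, match(fa, ind_ids)]
    for (kid in gme$probands) {
      k <- counts[, kid]
      hap <- haploid[, match(kid, ind_ids)]
      hom <- rare_site & !hap & !fhap & k == 2 & m == 1 & f == 1
      hemi <- rare_site & hap & k == 1 & m == 1 & f == 0
      het <- rare_site & !hap & k == 1
      mat <- het & m >= 1 & f == 0
      pat <- het & f >= 1 & m == 0
      ch <- rep(FALSE, S); cls <- character(S)
      for (g in unique(sites$gene[mat | pat])) {
        gi <- sites$gene == g
        if (any(mat & gi) && any(pat & gi)) {
          ch[(mat | pat) & gi] <- TRUE
          cls[mat & gi] <- "comphet_partner_a"
          cls[pat & gi] <- "comphet_partner_b"
        }
      }
      idx <- which(hom | hemi | ch)
      if (length(idx) > 0) {
        extra[[length(extra) + 1]] <- data.frame(
          proband_id = kid, chrom = sites$chrom[idx], pos = sites$pos[idx],
          ref = sites$ref[idx], alt = sites$alt[idx], gene = sites$gene[idx],
          consequence = sites$consequence[idx],
          class = ifelse(hom[idx], "homozygous",
                         ifelse(hemi[idx], "hemizygous", cls[idx])),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(extra) > 0) {
    truth <- rbind(truth, do.call(rbind, extra))
    tkey <- paste(truth$proband_id, truth$chrom, truth$pos, truth$ref,
                  truth$alt, sep = "\r")
    truth <- truth[!duplicated(tkey), , drop = FALSE]  # injected rows first
    rownames(truth) <- NULL
  }

  gt_of <- function(cnt, hap) {
    ifelse(hap, ifelse(cnt >= 1L, "hemi_alt", "hemi_ref"),
           c("hom_ref", "het", "hom_alt")[pmin(cnt, 2L) + 1L])
  }

  # ---- observation layer ---------------------------------------------------
  calls <- vector("list", N)
  cd <- config$depth_model
  for (j in seq_len(N)) {
    gt_true <- gt_of(counts[, j], haploid[, j])
    gt_obs <- gt_true
    if (config$genotype_error > 0) {
      err <- runif(S) < config$genotype_error
      gt_obs[err & gt_true == "het"] <- "hom_ref"
      gt_obs[err & gt_true == "hom_ref"] <- "het"
      gt_obs[err & gt_true == "hom_alt"] <- "het"
    }
    frac <- c(hom_ref = 0, het = 0.5, hom_alt = 1,
              hemi_ref = 0, hemi_alt = 1)[gt_obs]
    mk <- paste(ind_ids[j], sites$chrom, sites$pos, sites$ref, sites$alt,
                sep = "\r") %in% mosaic_keys
    frac[mk] <- config$mosaic_fraction
    if (config$noiseless) {
      dp <- rep(as.integer(round(cd$mean)), S)
      ad_alt <- as.integer(round(dp * frac))
      gq <- rep(99L, S)
    } else {
      dp <- pmax(4L, rnbinom(S, mu = cd$mean, size = cd$size))
      p_alt <- pmin(pmax(frac, config$error_rate), 1 - config$error_rate)
      ad_alt <- rbinom(S, dp, p_alt)
      gq <- pmax(1L, pmin(99L, as.integer(round(rnorm(S, 65, 18)))))
    }
    calls[[j]] <- data.frame(
      chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
      gene = sites$gene, consequence = sites$consequence,
      population_af = sites$population_af,
      individual_id = ind_ids[j], gt = gt_obs,
      ad_ref = dp - ad_alt, ad_alt = ad_alt, depth = dp, gq = gq,
      stringsAsFactors = FALSE)
  }
  base_calls <- do.call(rbind, calls)

  # per-caller views: independent dropout, occasional inflated genotype
  per_caller <- lapply(caller_labels(), function(cl) {
    cc <- base_calls
    cc$callers <- cl
    cc$discordant <- FALSE
    if (config$caller_discordance > 0) {
      flip <- runif(nrow(cc)) < config$caller_discordance & cc$gt == "het"
      cc$gt[flip] <- "hom_alt"
    }
    if (config$caller_dropout > 0) {
      cc <- cc[runif(nrow(cc)) >= config$caller_dropout, , drop = FALSE]
    }
    cc
  })
  names(per_caller) <- caller_labels()
  calls_long <- do.call(rbind, lapply(caller_labels(), function(cl) {
    cbind(per_caller[[cl]], caller = cl, stringsAsFactors = FALSE)
  }))
  rownames(calls_long) <- NULL

  # truth bookkeeping: was the proband's record dropped by all callers?
  tk <- paste(truth$proband_id, truth$chrom, truth$pos, truth$ref, truth$alt,
              sep = "\r")
  ck <- paste(calls_long$individual_id, calls_long$chrom, calls_long$pos,
              calls_long$ref, calls_long$alt, sep = "\r")
  truth$dropped <- !(tk %in% ck)

  cnv <- .sim_cnvs(cohort, gm, config)
  phen <- .sim_phenotypes(cohort, config)
  evid <- .sim_evidence(cohort, truth, phen, config)

  structure(list(config = config, cohort = cohort, gene_model = gm,
                 sites = sites, calls = calls_long, truth = truth, cnv = cnv,
                 phenotypes = phen, evidence = evid),
            class = "trio_simulation")
}

# pedigree construction: quads first (MZ pairs first among them), then trios
.sim_pedigree <- function(config) {
  rows <- list(); genomes <- list()
  fam_i <- 0
  add_family <- function(n_kids, mz) {
    fam_i <<- fam_i + 1
    fam <- sprintf("FAM%03d", fam_i)
    mo <- sprintf("M%03d", fam_i); fa <- sprintf("P%03d", fam_i)
    rows[[length(rows) + 1]] <<- data.frame(
      individual_id = c(mo, fa), family_id = fam, father_id = "0",
      mother_id = "0", sex = c("female", "male"), affected = FALSE,
      mz_twin_of = NA_character_, stringsAsFactors = FALSE)
    kid_sex <- if (mz) rep(sample(c("male", "female"), 1), n_kids) else
      sample(c("male", "female"), n_kids, replace = TRUE)
    kid_ids <- sprintf("F%03d%s", fam_i, c("", "B")[seq_len(n_kids)])
    twin_of <- rep(NA_character_, n_kids)
    if (mz && n_kids == 2) twin_of <- rev(kid_ids)
    rows[[length(rows) + 1]] <<- data.frame(
      individual_id = kid_ids, family_id = fam, father_id = fa,
      mother_id = mo, sex = kid_sex, affected = TRUE, mz_twin_of = twin_of,
      stringsAsFactors = FALSE)
    if (mz) {
      genomes[[length(genomes) + 1]] <<-
        list(probands = kid_ids, family = fam, sex = kid_sex[1])
    } else {
      for (k in seq_len(n_kids)) {
        genomes[[length(genomes) + 1]] <<-
          list(probands = kid_ids[k], family = fam, sex = kid_sex[k])
      }
    }
  }
  for (q in seq_len(config$n_quads)) add_family(2, q <= config$n_mz_twin_pairs)
  for (t in seq_len(config$n_trios)) add_family(1, FALSE)
  list(cohort = cohort(do.call(rbind, rows)), genomes = genomes)
}

# CNV calls: pathogenic-configuration injections plus benign noise classes
.sim_cnvs <- function(cohort, gm, config) {
  members <- cohort$members
  pro <- members[members$role == "proband", ]
  coding_x <- gm[gm$chrom == "X" & gm$biotype == "protein_coding" &
                   is_x_nonpar("X", gm$start, config$par), , drop = FALSE]
  coding_aut <- gm[gm$chrom != "X" & gm$biotype == "protein_coding", , drop = FALSE]

  mk_call <- function(id, pid, grow, type, conf, p, m, f, label) {
    fam <- members$family_id[match(pid, members$individual_id)]
    pad <- as.integer(round(runif(2, 1e3, 2e4)))
    data.frame(call_id = id, family_id = fam, proband_id = pid,
               chrom = grow$chrom, start = pmax(1L, grow$start - pad[1]),
               end = grow$end + pad[2], cnv_type = type,
               confidence = round(conf, 2), proband_carrier = p,
               mother_carrier = m, father_carrier = f,
               truth = label, stringsAsFactors = FALSE)
  }
  calls <- list(); i <- 0
  nid <- function() {i <<- i + 1; sprintf("CNV%03d", i)}

  # pathogenic configurations
  if (nrow(coding_x) >= 2 && nrow(pro) >= 3) {
    p1 <- pro$individual_id[1]
    calls[[length(calls) + 1]] <- mk_call(nid(), p1, coding_x[1, ], "deletion",
                                          runif(1, 15, 40), TRUE, FALSE, FALSE,
                                          "pathogenic_config")
    males <- pro$individual_id[pro$sex == "male"]
    if (length(males) > 0) {
      calls[[length(calls) + 1]] <- mk_call(nid(), males[1], coding_x[2, ],
                                            "deletion", runif(1, 15, 40),
                                            TRUE, TRUE, FALSE,
                                            "pathogenic_config")
    }
    p3 <- pro$individual_id[3]
    calls[[length(calls) + 1]] <- mk_call(nid(), p3,
                                          coding_aut[sample(nrow(coding_aut), 1), ],
                                          "deletion", runif(1, 15, 40),
                                          TRUE, TRUE, TRUE, "pathogenic_config")
  }
  # common catalog and a call matching it
  cat_rows <- coding_aut[sample(nrow(coding_aut), min(10, nrow(coding_aut))), ]
  catalog <- data.frame(chrom = cat_rows$chrom,
                        start = pmax(1L, cat_rows$start - 5000L),
                        end = cat_rows$end + 5000L, stringsAsFactors = FALSE)
  pid <- pro$individual_id[2]
  common_hit <- data.frame(call_id = nid(),
                           family_id = members$family_id[match(pid, members$individual_id)],
                           proband_id = pid, chrom = catalog$chrom[1],
                           start = catalog$start[1] + 1000L,
                           end = catalog$end[1] - 1000L,
                           cnv_type = "duplication", confidence = 25,
                           proband_carrier = TRUE, mother_carrier = FALSE,
                           father_carrier = FALSE, truth = "benign_common",
                           stringsAsFactors = FALSE)
  calls[[length(calls) + 1]] <- common_hit
  # low-confidence noise and an intergenic call and a dominant-inconsistent call
  for (k in 1:5) {
    grow <- coding_aut[sample(nrow(coding_aut), 1), ]
    calls[[length(calls) + 1]] <- mk_call(nid(), pro$individual_id[k %% nrow(pro) + 1],
                                          grow, "duplication",
                                          rnorm(1, 5, 2), TRUE, FALSE, FALSE,
                                          "benign_low_confidence")
  }
  pid <- pro$individual_id[min(4, nrow(pro))]
  fam <- members$family_id[match(pid, members$individual_id)]
  calls[[length(calls) + 1]] <- data.frame(
    call_id = nid(), family_id = fam, proband_id = pid, chrom = "2",
    start = 10L, end = 5000L, cnv_type = "deletion", confidence = 30,
    proband_carrier = TRUE, mother_carrier = FALSE, father_carrier = FALSE,
    truth = "benign_intergenic", stringsAsFactors = FALSE)
  grow <- coding_aut[sample(nrow(coding_aut), 1), ]
  calls[[length(calls) + 1]] <- mk_call(nid(), pro$individual_id[1], grow,
                                        "deletion", 30, TRUE, FALSE, TRUE,
                                        "benign_mode_inconsistent")
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  truth <- calls[, c("call_id", "truth")]
  calls$truth <- NULL
  list(calls = calls, common_catalog = catalog, truth = truth)
}

.sim_phenotypes <- function(cohort, config) {
  leaves <- .sim_hpo_leaves()
  pro <- probands(cohort)
  terms <- lapply(pro, function(p) sort(sample(leaves, sample(2:5, 1))))
  data.frame(proband_id = pro,
             source = sample(c("ultrasound", "postmortem", "pediatric"),
                             length(pro), replace = TRUE,
                             prob = c(0.6, 0.25, 0.15)),
             hpo_terms = I(terms), stringsAsFactors = FALSE)
}

.sim_evidence <- function(cohort, truth, phenotypes, config) {
  cols <- data.frame(gene = character(0), known_human_disease_gene = logical(0),
                     disease_hpo = character(0),
                     identical_variant_reported_pathogenic = logical(0),
                     damaging_variant_class_in_known_domain = logical(0),
                     dosage_sensitive_loss = logical(0),
                     model_organism_phenotype_overlap = logical(0),
                     functional_plausibility = logical(0),
                     expression_relevant = logical(0), stringsAsFactors = FALSE)
  dn <- truth[truth$class %in% c("de_novo", "mosaic_de_novo"), , drop = FALSE]
  if (nrow(dn) == 0 || config$diagnostic_fraction <= 0) return(cols)
  pro <- unique(dn$proband_id)
  n_dx <- max(0L, round(length(probands(cohort)) * config$diagnostic_fraction))
  dx <- head(sample(pro), n_dx)
  rows <- lapply(dx, function(p) {
    gene <- dn$gene[dn$proband_id == p][1]
    terms <- phenotypes$hpo_terms[[match(p, phenotypes$proband_id)]]
    data.frame(gene = gene, known_human_disease_gene = TRUE,
               disease_hpo = paste(terms, collapse = ";"),
               identical_variant_reported_pathogenic = TRUE,
               damaging_variant_class_in_known_domain = FALSE,
               dosage_sensitive_loss = FALSE,
               model_organism_phenotype_overlap = TRUE,
               functional_plausibility = TRUE, expression_relevant = TRUE,
               stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, rows))
}

#' Per-caller call sets for one individual from a simulation
#'
#' @param sim A `trio_simulation`.
#' @param individual_id Individual id.
#' @return Named list of call-set data frames, one per caller.
#' @export
sim_caller_callsets <- function(sim, individual_id) {
  cc <- sim$calls[sim$calls$individual_id == individual_id, , drop = FALSE]
  out <- split(cc[, setdiff(names(cc), "caller")], cc$caller)
  lapply(out, function(x) {row.names(x) <- NULL; x})
}

#' Merged (multi-caller) call sets for every individual in a simulation
#'
#' Runs [merge_caller_calls()] per individual.
#'
#' @param sim A `trio_simulation`.
#' @return Named list of unified call-set data frames.
#' @export
sim_merged_callsets <- function(sim) {
  ids <- sim$cohort$members$individual_id
  out <- lapply(ids, function(id) merge_caller_calls(sim_caller_callsets(sim, id)))
  names(out) <- ids
  out
}

#' Trio genotype table straight from a simulation
#'
#' Convenience wrapper: merge per-caller call sets for every individual and
#' assemble trio records.
#'
#' @param sim A `trio_simulation`.
#' @return Trio genotype data frame, see [build_trio_genotypes()].
#' @export
sim_trios <- function(sim) {
  build_trio_genotypes(sim_merged_callsets(sim), sim$cohort)
}

#' Write a simulated cohort bundle to disk
#'
#' Emits the dialects the readers consume: PED pedigree, phenotype TSV,
#' per-individual per-caller VCFs under `calls/`, CNV call TSV, common-CNV
#' catalog BED, gene model BED, gene-evidence TSV, truth TSV and the resolved
#' configuration as YAML. Output is deterministic given the simulation.
#'
#' @param sim A `trio_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort_bundle <- function(sim, dir) {
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    pedigree = file.path(dir, "pedigree.ped"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.tsv"),
    gene_model = file.path(dir, "gene_model.bed"),
    cnv_calls = file.path(dir, "cnv_calls.tsv"),
    cnv_common = file.path(dir, "cnv_common.bed"),
    cnv_truth = file.path(dir, "cnv_truth.tsv"),
    evidence = file.path(dir, "gene_evidence.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_pedigree(sim$cohort, paths$pedigree)
  write_phenotypes(sim$phenotypes, paths$phenotypes)
  write_truth(sim$truth, paths$truth)
  gm <- sim$gene_model
  write.table(gm[, c("chrom", "start", "end", "gene", "biotype")],
              paths$gene_model, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$cnv$calls, paths$cnv_calls, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$cnv$common_catalog, paths$cnv_common, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$cnv$truth, paths$cnv_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$evidence, paths$evidence, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- sim$config
  cfg$par <- lapply(cfg$par, as.integer)
  yaml::write_yaml(unclass(cfg), paths$config)
  vcfs <- character(0)
  for (id in sim$cohort$members$individual_id) {
    for (cl in caller_labels()) {
      cs <- sim$calls[sim$calls$individual_id == id & sim$calls$caller == cl,
                      setdiff(names(sim$calls), "caller"), drop = FALSE]
      p <- file.path(dir, "calls", paste0(id, ".", cl, ".vcf"))
      write_callset_vcf(cs, p, source_label = cl)
      vcfs <- c(vcfs, p)
    }
  }
  paths$vcfs <- vcfs
  invisible(paths)
}

#' Write / read a truth table
#'
#' The truth table records every injected event (de novo, mosaic de novo,
#' compound-het partners, homozygous, hemizygous) with its proband, site and
#' whether all callers dropped the proband's record. TSV round trips are
#' lossless.
#'
#' @param truth Truth data frame from [simulate_cohort()].
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the data frame.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", ref = "character",
                            alt = "character"))
}

#' Validation statuses for de novo candidates from a simulation truth table
#'
#' Emulates orthogonal validation on simulated data: candidates present in
#' the truth table as (mosaic) de novo events are `validated`, all others
#' `refuted`.
#'
#' @param candidates A `denovo_candidates` data frame.
#' @param truth Truth table from [simulate_cohort()].
#' @return Status data frame suitable for [apply_validation()].
#' @export
truth_validation_table <- function(candidates, truth) {
  tk <- paste(truth$proband_id, truth$chrom, truth$pos, truth$ref, truth$alt,
              sep = "\r")
  tk <- tk[truth$class %in% c("de_novo", "mosaic_de_novo")]
  ck <- paste(candidates$proband_id, candidates$chrom, candidates$pos,
              candidates$ref, candidates$alt, sep = "\r")
  data.frame(proband_id = candidates$proband_id, chrom = candidates$chrom,
             pos = candidates$pos, ref = candidates$ref,
             alt = candidates$alt,
             status = ifelse(ck %in% tk, "validated", "refuted"),
             stringsAsFactors = FALSE)
}
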