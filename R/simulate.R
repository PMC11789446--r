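#' Configuration of the synthetic annotated-variant cohort generator
#'
#' Describes a cohort of index cases whose annotated variants have known,
#' configurable behavior at every cascade gate. Each gate's marginal pass
#' probability equals the configured value exactly: the generator first
#' draws the gate outcome as a Bernoulli variable and then draws scores
#' from the side of the threshold that realizes it (inverse construction),
#' so closed-form survivor expectations are available as a test oracle via
#' [expected_survivors()]. Defaults describe a nine-family study at desk
#' scale with a realistic post-annotation class mix dominated by missense
#' and synonymous/intronic ("other") calls and stringent rarity /
#' deleteriousness gates.
#'
#' @param n_families Number of index cases.
#' @param variants_per_family Annotated variants per index case.
#' @param class_mix Named probabilities over
#'   `MISSENSE, STOP_GAIN, FRAMESHIFT, CANONICAL_SPLICE, OTHER`; must sum
#'   to 1.
#' @param maf_pass Marginal probability that a variant passes the
#'   allele-frequency gate.
#' @param novel_frac Fraction of frequency-gate passers carrying no gnomAD
#'   record at all (novel alleles).
#' @param cadd_pass Marginal probability of passing the CADD gate.
#' @param vote_pass Marginal probability that a missense variant passes the
#'   nine-tool deleteriousness vote.
#' @param concordance Tool concordance in `[0.5, 1]`: how tightly the
#'   number of deleterious calls concentrates near 9 (for vote passers) or
#'   0 (for failers), implemented as a shared latent pathogenicity state
#'   with per-tool binomial noise.
#' @param conservation_pass Marginal probability that a missense variant
#'   collects >= 2 conservation votes.
#' @param last_exon_frac Fraction of truncating variants falling in the
#'   last exon (these are excluded by the cascade).
#' @param lof_scored Probability that a truncating variant carries a
#'   MutPred2 score and a splice variant carries SpliceAI/MMSplice scores.
#' @param seed Mandatory RNG seed.
#' @param thresholds The [threshold_config()] whose cutoffs the score
#'   distributions are inverted against.
#' @return A `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_families = 9L,
                              variants_per_family = 1000L,
                              class_mix = c(MISSENSE = 0.55,
                                            STOP_GAIN = 0.03,
                                            FRAMESHIFT = 0.04,
                                            CANONICAL_SPLICE = 0.02,
                                            OTHER = 0.36),
                              maf_pass = 0.15,
                              novel_frac = 0.3,
                              cadd_pass = 0.10,
                              vote_pass = 0.30,
                              concordance = 0.8,
                              conservation_pass = 0.5,
                              last_exon_frac = 0.10,
                              lof_scored = 0.8,
                              seed,
                              thresholds = threshold_config()) {
  if (missing(seed)) stop("a seed is mandatory for the cohort generator")
  probs <- c(maf_pass, novel_frac, cadd_pass, vote_pass, conservation_pass,
             last_exon_frac, lof_scored)
  stopifnot(all(probs >= 0 & probs <= 1),
            concordance >= 0.5, concordance <= 1,
            n_families >= 1, variants_per_family >= 0,
            setequal(names(class_mix),
                     c("MISSENSE", "STOP_GAIN", "FRAMESHIFT",
                       "CANONICAL_SPLICE", "OTHER")),
            abs(sum(class_mix) - 1) < 1e-8)
  structure(list(
    n_families = as.integer(n_families),
    variants_per_family = as.integer(variants_per_family),
    class_mix = class_mix[c("MISSENSE", "STOP_GAIN", "FRAMESHIFT",
                            "CANONICAL_SPLICE", "OTHER")],
    maf_pass = maf_pass, novel_frac = novel_frac, cadd_pass = cadd_pass,
    vote_pass = vote_pass, concordance = concordance,
    conservation_pass = conservation_pass,
    last_exon_frac = last_exon_frac, lof_scored = lof_scored,
    seed = as.integer(seed), thresholds = as_threshold_config(thresholds)),
    class = "cohort_sim_config")
}

#' Generate a synthetic annotated cohort with ground-truth gate labels
#'
#' Emits a cohort table in the package's TSV dialect together with a truth
#' table recording, per variant, the gate outcomes that were planted. Fully
#' deterministic given the config's seed (one RNG stream, fixed generation
#' order).
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list: `cohort` (a `variant_table`), `truth` (data.frame with
#'   planted per-gate outcomes and `survives`), `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  t <- cfg$thresholds
  n <- cfg$n_families * cfg$variants_per_family
  if (n == 0) {
    return(list(cohort = variant_table(cbind(empty_cohort())),
                truth = data.frame(), config = cfg))
  }
  family_id <- rep(paste0("F", seq_len(cfg$n_families)),
                   each = cfg$variants_per_family)
  vclass <- sample(names(cfg$class_mix), n, replace = TRUE,
                   prob = cfg$class_mix)
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(2e8, n)  # without replacement: unique variant ids
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  is_fs <- vclass == "FRAMESHIFT"
  ref[is_fs] <- paste0(ref[is_fs],
                       sample(bases, sum(is_fs), replace = TRUE))
  alt[is_fs] <- substr(ref[is_fs], 1, 1)
  gene_symbol <- sprintf("GENE%05d", sample.int(60000, n))
  consequence <- c(MISSENSE = "missense_variant",
                   STOP_GAIN = "stop_gained",
                   FRAMESHIFT = "frameshift_variant",
                   OTHER = "synonymous_variant")[vclass]
  is_sp <- vclass == "CANONICAL_SPLICE"
  consequence[is_sp] <- sample(c("splice_donor_variant",
                                 "splice_acceptor_variant"),
                               sum(is_sp), replace = TRUE)

  ## frequency gate: planted outcome, then scores on the matching side
  maf_ok <- stats::runif(n) < cfg$maf_pass
  novel <- maf_ok & stats::runif(n) < cfg$novel_frac
  draw_af <- function(ok) {
    af <- matrix(NA_real_, n, 3)
    lo_rows <- which(ok & !novel)
    af[lo_rows, ] <- stats::runif(3 * length(lo_rows), 0,
                                  t$maf_max * 0.999)
    hi_rows <- which(!ok)
    af[hi_rows, ] <- stats::runif(3 * length(hi_rows), t$maf_max, 0.05)
    af
  }
  af <- draw_af(maf_ok)

  cadd_ok <- stats::runif(n) < cfg$cadd_pass
  cadd <- ifelse(cadd_ok,
                 stats::runif(n, t$cadd_min + 1e-4, 45),
                 stats::runif(n, 0, t$cadd_min))

  ## deleteriousness vote: latent pathogenic state + per-tool noise, with
  ## the number of deleterious calls forced to the planted side of 4.5
  tools <- predictor_tools()
  vote_ok <- stats::runif(n) < cfg$vote_pass
  n_del <- ifelse(vote_ok,
                  5L + stats::rbinom(n, 4, cfg$concordance),
                  stats::rbinom(n, 4, 1 - cfg$concordance))
  calls <- matrix(NA_character_, n, length(tools),
                  dimnames = list(NULL, paste0("call_", tools)))
  mis_rows <- which(vclass == "MISSENSE")
  for (i in mis_rows) {
    del <- sample(length(tools), n_del[i])
    ci <- rep("tolerated", length(tools))
    ci[del] <- "deleterious"
    nd <- setdiff(seq_along(tools), del)
    if (length(nd) > 0 && stats::runif(1) < 0.2) {
      ci[sample(nd, 1)] <- "missing"  # missing calls contribute nothing
    }
    calls[i, ] <- ci
  }

  cons_ok <- stats::runif(n) < cfg$conservation_pass
  n_votes <- ifelse(cons_ok, 2L + stats::rbinom(n, 1, 0.5),
                    stats::rbinom(n, 1, 0.5))
  gerp <- rep(NA_real_, n); phastcons <- rep(NA_real_, n)
  phylop <- rep(NA_real_, n)
  for (i in mis_rows) {
    voters <- sample(3, n_votes[i])
    gerp[i] <- if (1 %in% voters) stats::runif(1, t$gerp_min + 1e-4, 6) else
      stats::runif(1, -3, t$gerp_min)
    phastcons[i] <- if (2 %in% voters) stats::runif(1, t$phastcons_min + 1e-4, 1) else
      stats::runif(1, 0, t$phastcons_min)
    phylop[i] <- if (3 %in% voters) stats::runif(1, t$phylop_min, 9) else
      stats::runif(1, -3, t$phylop_min - 1e-4)
  }
  missense_z <- ifelse(vclass == "MISSENSE", stats::rnorm(n, 1, 1.5),
                       NA_real_)
  alphamissense <- ifelse(vclass == "MISSENSE", stats::rbeta(n, 2, 2),
                          NA_real_)
  revel <- ifelse(vclass == "MISSENSE", stats::rbeta(n, 2, 2), NA_real_)

  ## truncating variants: exon geometry and LoF evidence
  trunc <- vclass %in% c("STOP_GAIN", "FRAMESHIFT")
  in_last <- trunc & stats::runif(n) < cfg$last_exon_frac
  exon_total <- ifelse(trunc, sample(3:20, n, replace = TRUE), NA_integer_)
  exon_index <- rep(NA_integer_, n)
  exon_index[trunc & in_last] <- exon_total[trunc & in_last]
  not_last <- which(trunc & !in_last)
  exon_index[not_last] <- vapply(exon_total[not_last],
                                 function(tt) sample.int(tt - 1L, 1),
                                 integer(1))
  mutpred2 <- rep(NA_real_, n)
  sc <- trunc & stats::runif(n) < cfg$lof_scored
  mutpred2[sc] <- round(stats::rbeta(sum(sc), 2.5, 2.5), 3)
  loeuf <- ifelse(trunc | is_sp, round(stats::runif(n, 0.1, 1.5), 3),
                  NA_real_)

  spl <- matrix(NA_real_, n, 4)
  mmsplice <- rep(NA_real_, n)
  sp_sc <- which(is_sp & stats::runif(n) < cfg$lof_scored)
  for (i in sp_sc) {
    d <- stats::runif(4, 0, 0.15)
    d[sample(4, 1)] <- stats::runif(1, 0.3, 1)
    spl[i, ] <- round(d, 3)
    mmsplice[i] <- round(stats::rnorm(1, -2, 2), 3)
  }

  cohort <- data.frame(
    variant_id = paste(chrom, pos, ref, alt, sep = "_"),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    family_id = family_id, gene_symbol = gene_symbol,
    transcript_id = sprintf("ENST%011d", seq_len(n)),
    is_canonical = TRUE, consequence_terms = consequence,
    exon_index = exon_index, exon_total = exon_total,
    af_global = af[, 1], af_nfe = af[, 2], af_popmax = af[, 3],
    cadd_phred = round(cadd, 2),
    gerp = round(gerp, 3), phastcons = round(phastcons, 4),
    phylop = round(phylop, 3),
    missense_z = round(missense_z, 2),
    alphamissense = round(alphamissense, 3), revel = round(revel, 3),
    mutpred2_score = mutpred2,
    spliceai_ag = spl[, 1], spliceai_al = spl[, 2],
    spliceai_dg = spl[, 3], spliceai_dl = spl[, 4],
    mmsplice = mmsplice,
    loeuf = loeuf,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(calls, stringsAsFactors = FALSE))

  survives <- maf_ok & cadd_ok &
    ifelse(vclass == "MISSENSE", vote_ok & cons_ok,
           ifelse(trunc, !in_last, is_sp))
  truth <- data.frame(
    variant_id = cohort$variant_id, variant_class = vclass,
    maf_pass = maf_ok, cadd_pass = cadd_ok,
    vote_pass = ifelse(vclass == "MISSENSE", vote_ok, NA),
    conservation_pass = ifelse(vclass == "MISSENSE", cons_ok, NA),
    in_last_exon = ifelse(trunc, in_last, NA),
    survives = survives)
  list(cohort = variant_table(cohort), truth = truth, config = cfg)
}

#' Closed-form expected survivor counts per class
#'
#' Because the generator plants independent gate outcomes with exact
#' marginal probabilities, the expected survivor count of each class is a
#' product over that class's gate route, times the expected class count;
#' the realized count is Binomial(total, class share x route probability).
#' Used as the analytic oracle for cascade recovery tests.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A data.frame per class: `n_expected` (expected class size),
#'   `p_route` (survival probability given the class), `expected`
#'   (expected survivors) and `sd` (binomial standard deviation of the
#'   survivor count).
#' @export
expected_survivors <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  n <- cfg$n_families * cfg$variants_per_family
  mix <- cfg$class_mix
  route <- c(
    MISSENSE = cfg$maf_pass * cfg$cadd_pass * cfg$vote_pass *
      cfg$conservation_pass,
    STOP_GAIN = cfg$maf_pass * cfg$cadd_pass * (1 - cfg$last_exon_frac),
    FRAMESHIFT = cfg$maf_pass * cfg$cadd_pass * (1 - cfg$last_exon_frac),
    CANONICAL_SPLICE = cfg$maf_pass * cfg$cadd_pass,
    OTHER = 0)
  q <- mix * route[names(mix)]
  data.frame(
    variant_class = names(mix),
    n_expected = unname(n * mix),
    p_route = unname(route[names(mix)]),
    expected = unname(n * q),
    sd = unname(sqrt(n * q * (1 - q))),
    row.names = NULL)
}

#' Configuration of the synthetic PPI network and gene-set generator
#'
#' A planted-partition interactome: `n_modules` modules of given sizes with
#' dense, high-confidence within-module edges and sparse, low-confidence
#' between-module edges, plus one annotation term per module and decoy
#' terms of matched size, so cluster recovery and enrichment can be scored
#' against ground truth.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Nodes per module (scalar or vector).
#' @param p_within,p_between Edge probabilities (within must exceed
#'   between).
#' @param within_range,between_range Ranges of the dominant channel score
#'   for within- and between-module edges.
#' @param n_decoys Decoy gene sets per planted term.
#' @param seed Mandatory RNG seed.
#' @return A `network_sim_config`.
#' @export
network_sim_config <- function(n_modules = 4L, module_size = 10L,
                               p_within = 0.9, p_between = 0.03,
                               within_range = c(0.7, 0.95),
                               between_range = c(0.42, 0.55),
                               n_decoys = 3L, seed) {
  if (missing(seed)) stop("a seed is mandatory for the network generator")
  sizes <- rep_len(as.integer(module_size), n_modules)
  stopifnot(p_within > p_between, p_within <= 1, p_between >= 0,
            all(sizes >= 2))
  structure(list(n_modules = as.integer(n_modules), module_sizes = sizes,
                 p_within = p_within, p_between = p_between,
                 within_range = within_range, between_range = between_range,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "network_sim_config")
}

#' Generate a planted-partition network with matched gene sets
#'
#' @param cfg A [network_sim_config()].
#' @return A list: `edges` (STRING-style channel-score table), `genes`,
#'   `membership` (named integer vector, the planted module of each gene),
#'   `sets` (a `gene_set_collection` with one `MODULE_k` term per planted
#'   module plus decoys) and `truth` (planted term ids and parameters).
#' @export
generate_network_and_sets <- function(cfg) {
  stopifnot(inherits(cfg, "network_sim_config"))
  set.seed(cfg$seed)
  sizes <- cfg$module_sizes
  genes <- unlist(lapply(seq_along(sizes), function(m) {
    sprintf("M%02dG%02d", m, seq_len(sizes[m]))
  }))
  membership <- stats::setNames(rep(seq_along(sizes), sizes), genes)
  n <- length(genes)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same <- membership[i] == membership[j]
      p <- if (same) cfg$p_within else cfg$p_between
      if (stats::runif(1) >= p) next
      rng <- if (same) cfg$within_range else cfg$between_range
      ch <- stats::runif(3, 0, 0.1)
      ch[sample(3, 1)] <- stats::runif(1, rng[1], rng[2])
      rows[[length(rows) + 1]] <- data.frame(
        protein_a = genes[i], protein_b = genes[j],
        experiments = round(ch[1], 3), database = round(ch[2], 3),
        coexpression = round(ch[3], 3))
    }
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(protein_a = character(), protein_b = character(),
               experiments = numeric(), database = numeric(),
               coexpression = numeric())

  terms <- list(); members <- list()
  for (m in seq_along(sizes)) {
    id <- sprintf("MODULE_%02d", m)
    terms[[length(terms) + 1]] <- data.frame(
      term_id = id, term_name = paste("planted module", m),
      collection = "planted")
    members[[id]] <- genes[membership == m]
    for (d in seq_len(cfg$n_decoys)) {
      did <- sprintf("DECOY_%02d_%02d", m, d)
      terms[[length(terms) + 1]] <- data.frame(
        term_id = did, term_name = paste("decoy", m, d),
        collection = "planted")
      members[[did]] <- sample(genes, sizes[m])
    }
  }
  sets <- gene_set_collection(do.call(rbind, terms), members,
                              background = genes)
  list(edges = edges, genes = genes, membership = membership, sets = sets,
       truth = list(planted_terms = sprintf("MODULE_%02d",
                                            seq_along(sizes)),
                    module_sizes = sizes, p_within = cfg$p_within,
                    p_between = cfg$p_between, seed = cfg$seed))
}
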