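#' Default planted emission matrix
#'
#' Six chromatin states over five histone marks plus DNase, echoing the
#' canonical plant chromatin-state repertoire: S1 Polycomb (H3K27me3), S2
#' quiescent (no marks), S3 open chromatin only, S4 active promoter-like
#' (H3K4me3 + acetylation + open), S5 acetylation-dominated open chromatin,
#' S6 transcribed but inaccessible (H3K4me3 + H3K36me3, no DNase).
#'
#' @return 6 x 6 matrix of Bernoulli emission probabilities.
#' @export
default_emission <- function() {
  marks <- c("H3K4me3", "H3K27me3", "H3K36me3", "H3K27ac", "H3K9ac", "DNase")
  em <- rbind(
    S1 = c(0.05, 0.90, 0.05, 0.03, 0.03, 0.05),
    S2 = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    S3 = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.90),
    S4 = c(0.80, 0.02, 0.10, 0.70, 0.70, 0.80),
    S5 = c(0.30, 0.05, 0.10, 0.90, 0.90, 0.85),
    S6 = c(0.80, 0.05, 0.85, 0.10, 0.10, 0.05))
  colnames(em) <- marks
  em
}

#' Default planted transition matrix
#'
#' Sticky chain dominated by the quiescent state: every state strongly
#' self-transitions, and mass leaving a marked state flows mainly back to
#' S2, so the quiescent state covers most of the genome at stationarity.
#'
#' @return 6 x 6 row-stochastic matrix.
#' @export
default_transition <- function() {
  K <- 6
  tr <- matrix(0.01, K, K)
  diag(tr) <- 0.90
  tr[, 2] <- 0.06
  tr[2, ] <- 0.005
  diag(tr) <- 0
  diag(tr) <- 1 - rowSums(tr)
  dimnames(tr) <- list(paste0("S", 1:K), paste0("S", 1:K))
  tr
}

#' Simulation configuration
#'
#' Parameters of the synthetic allotetraploid dataset. Defaults describe a
#' toy genome with the structural features the pipeline targets: an A
#' subgenome twice the size of the D subgenome, a quiescent-dominated
#' chromatin-state chain, balanced homoeolog pairs with expression bias
#' confined to subgenome-unique genes, and promoter state switches between
#' conditions coupled to differential expression.
#'
#' @param seed RNG seed (all outputs are deterministic given it).
#' @param n_chroms chromosomes per subgenome, named \code{c(A=, D=)}.
#' @param chrom_length chromosome length per subgenome in bases.
#' @param bin_width chromatin bin width (default 200).
#' @param emission,transition planted K x M emission and K x K transition
#'   matrices.
#' @param rate_low,rate_high Poisson fragment rates per bin for unmarked /
#'   marked bins.
#' @param n_genes genes per subgenome.
#' @param homoeolog_fraction fraction of the smaller subgenome's genes in
#'   homoeolog pairs.
#' @param unique_fraction fraction of each subgenome's genes that are
#'   subgenome-unique.
#' @param new_gene_fraction fraction of genes flagged as polyploidy-derived
#'   new genes.
#' @param n_tes number of TE intervals.
#' @param te_class_probs TE class mixture.
#' @param expr_meanlog,expr_sdlog log-normal distribution of baseline gene
#'   expression means.
#' @param dispersion NB dispersion of expression counts.
#' @param a_bias_factor expression multiplier applied to A-subgenome-unique
#'   genes (pairs stay balanced).
#' @param de_fraction fraction of genes given a planted expression change
#'   between conditions (besides transition-coupled genes).
#' @param de_effect fold change of planted expression changes.
#' @param transition_fraction fraction of genes whose condition-2 promoter
#'   state is switched.
#' @param coupled_up_prob probability that a switch out of the quiescent
#'   state is coupled to upregulation (and a switch into it to
#'   downregulation).
#' @param n_reps sequencing replicates per condition.
#' @param conditions condition labels (wild, domesticated).
#' @return a \code{SimulationConfig} list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = c(A = 2L, D = 2L),
                              chrom_length = c(A = 1e6, D = 5e5),
                              bin_width = 200L,
                              emission = default_emission(),
                              transition = default_transition(),
                              rate_low = 0.2, rate_high = 6,
                              n_genes = c(A = 800L, D = 500L),
                              homoeolog_fraction = 0.7,
                              unique_fraction = 0.15,
                              new_gene_fraction = 0.1,
                              n_tes = 400L,
                              te_class_probs = c(Gypsy = 0.35, Copia = 0.2,
                                                 hAT = 0.1, Helitron = 0.1,
                                                 CACTA = 0.1,
                                                 other_retro = 0.1,
                                                 other_DNA = 0.05),
                              expr_meanlog = 5, expr_sdlog = 1,
                              dispersion = 0.05,
                              a_bias_factor = 2,
                              de_fraction = 0.2, de_effect = 4,
                              transition_fraction = 0.15,
                              coupled_up_prob = 0.8,
                              n_reps = 2L,
                              conditions = c("wild", "domesticated")) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$emission >= 0 & cfg$emission <= 1),
            all(abs(rowSums(cfg$transition) - 1) < 1e-9),
            homoeolog_fraction >= 0, homoeolog_fraction <= 1,
            unique_fraction >= 0, unique_fraction <= 1,
            new_gene_fraction >= 0, new_gene_fraction <= 1,
            de_fraction >= 0, de_fraction <= 1,
            transition_fraction >= 0, transition_fraction <= 1,
            coupled_up_prob >= 0, coupled_up_prob <= 1,
            abs(sum(te_class_probs) - 1) < 1e-9)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate the genome: layout, gene models and TEs
#'
#' Chromosome lengths give the A subgenome twice the D subgenome's size (at
#' the defaults). Genes are placed non-overlapping with at least 500 bp of
#' upstream clearance, on alternating strands; each gene gets 1-3 exons.
#' TE intervals are drawn uniformly with classes from the configured
#' mixture.
#'
#' @param config a [simulation_config()].
#' @return list with \code{layout}, \code{genes}, \code{exons}, \code{tes}.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  layout <- genome_layout(
    chrom = c(sprintf("A%02d", seq_len(config$n_chroms[["A"]])),
              sprintf("D%02d", seq_len(config$n_chroms[["D"]]))),
    length = c(rep(config$chrom_length[["A"]], config$n_chroms[["A"]]),
               rep(config$chrom_length[["D"]], config$n_chroms[["D"]])),
    subgenome = c(rep("A", config$n_chroms[["A"]]),
                  rep("D", config$n_chroms[["D"]])))
  genes_parts <- list()
  exons_parts <- list()
  for (sg in c("A", "D")) {
    chroms <- layout$chrom[layout$subgenome == sg]
    n_per <- ceiling(config$n_genes[[sg]] / length(chroms))
    counter <- 0L
    for (ch in chroms) {
      len <- chrom_length(layout, ch)
      # budget spacing so the requested density fits with clearance
      slot <- len / n_per
      if (slot < 1400) stop("infeasible gene density on ", ch)
      pos <- 600
      for (i in seq_len(n_per)) {
        if (counter >= config$n_genes[[sg]]) break
        glen <- round(stats::runif(1, 600, min(1200, slot - 700)))
        gap <- round(stats::runif(1, 600, max(601, slot - glen - 50)))
        if (pos + glen > len - 100) break
        counter <- counter + 1L
        gid <- sprintf("%s_g%04d", sg, counter)
        strand <- if (counter %% 2 == 0) "-" else "+"
        genes_parts[[length(genes_parts) + 1L]] <- data.frame(
          gene_id = gid, chrom = ch, start = pos, end = pos + glen,
          strand = strand, subgenome = sg, is_new_gene = FALSE,
          stringsAsFactors = FALSE)
        n_ex <- sample(1:3, 1)
        cuts <- sort(sample(seq(50, glen - 50, by = 10), 2 * (n_ex - 1)))
        bounds <- matrix(c(0, cuts, glen), ncol = 2, byrow = TRUE)
        exons_parts[[length(exons_parts) + 1L]] <- data.frame(
          gene_id = gid, chrom = ch, start = pos + bounds[, 1],
          end = pos + bounds[, 2], stringsAsFactors = FALSE)
        pos <- pos + glen + gap
      }
    }
    if (counter < config$n_genes[[sg]]) {
      stop("infeasible gene density: placed ", counter, " of ",
           config$n_genes[[sg]], " ", sg, "-subgenome genes")
    }
  }
  genes <- do.call(rbind, genes_parts)
  exons <- do.call(rbind, exons_parts)
  n_new <- round(config$new_gene_fraction * nrow(genes))
  genes$is_new_gene[sample.int(nrow(genes), n_new)] <- TRUE
  tes <- data.frame(
    chrom = sample(layout$chrom, config$n_tes, replace = TRUE,
                   prob = layout$length),
    stringsAsFactors = FALSE)
  te_len <- round(stats::runif(config$n_tes, 500, 3000))
  te_max <- chrom_length(layout, tes$chrom) - te_len
  tes$start <- floor(stats::runif(config$n_tes, 0, te_max))
  tes$end <- tes$start + te_len
  tes$te_class <- sample(names(config$te_class_probs), config$n_tes,
                         replace = TRUE, prob = config$te_class_probs)
  tes <- tes[order(tes$chrom, tes$start), ]
  rownames(tes) <- rownames(genes) <- rownames(exons) <- NULL
  list(layout = layout, genes = genes, exons = exons, tes = tes)
}

markov_path <- function(n, transition, initial) {
  K <- nrow(transition)
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = initial)
  cum <- t(apply(transition, 1, cumsum))
  u <- stats::runif(n)
  for (t in 2:n) s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
  s
}

#' Simulate chromatin-state tracks
#'
#' Draws a hidden state per 200-bp bin from the planted Markov chain,
#' switches the condition-2 promoter state of a planted fraction of genes,
#' and emits per-bin Poisson fragment counts for each mark, replicate and
#' condition (rate \code{rate_low} for unmarked bins, \code{rate_high}
#' scaled by the state's emission probability for marked bins), plus a Mock
#' control at the background rate.
#'
#' @param config a [simulation_config()].
#' @param genome a [simulate_genome()] result.
#' @return list with \code{tracks} (nested list
#'   \code{[[condition]][[mark]][[rep]]} of [binned_track()]s, Mock
#'   included), \code{truth_seg} (per-condition \code{Segmentation} of the
#'   planted states) and \code{planted_transitions} (data.frame
#'   \code{gene_id}, \code{state_from}, \code{state_to}).
#' @export
simulate_state_tracks <- function(config, genome) {
  set.seed(config$seed + 1L)
  layout <- genome$layout
  bw <- config$bin_width
  K <- nrow(config$emission)
  marks <- colnames(config$emission)
  nb <- n_bins(layout, bw)
  stat_init <- rep(1 / K, K)
  states1 <- lapply(layout$chrom, function(ch)
    markov_path(nb[[ch]], config$transition, stat_init))
  names(states1) <- layout$chrom
  states2 <- states1

  genes <- genome$genes
  prom <- promoter_intervals(genes, layout, 500L)
  n_switch <- round(config$transition_fraction * nrow(genes))
  switch_idx <- sort(sample.int(nrow(genes), n_switch))
  planted <- data.frame(gene_id = character(0), state_from = character(0),
                        state_to = character(0), coupled = character(0),
                        stringsAsFactors = FALSE)
  for (i in switch_idx) {
    s <- prom$start[i]; e <- prom$end[i]
    if (e <= s) next
    bins <- (s %/% bw):((e - 1) %/% bw) + 1L
    sv <- states1[[prom$chrom[i]]]
    from <- as.integer(names(which.max(table(sv[bins]))))
    to <- if (from == 2L && stats::runif(1) < 0.7) 3L else
      sample(setdiff(seq_len(K), from), 1)
    states2[[prom$chrom[i]]][bins] <- to
    coupled <- if (from == 2L) "up" else if (to == 2L) "down" else "none"
    planted <- rbind(planted, data.frame(
      gene_id = genes$gene_id[i], state_from = paste0("S", from),
      state_to = paste0("S", to), coupled = coupled,
      stringsAsFactors = FALSE))
  }

  all_states <- list(states1, states2)
  names(all_states) <- config$conditions
  tracks <- list()
  for (cond in config$conditions) {
    st <- all_states[[cond]]
    tracks[[cond]] <- list()
    for (mk in marks) {
      rate_by_state <- config$rate_low +
        config$emission[, mk] * (config$rate_high - config$rate_low)
      tracks[[cond]][[mk]] <- lapply(seq_len(config$n_reps), function(r) {
        counts <- lapply(layout$chrom, function(ch)
          stats::rpois(nb[[ch]], rate_by_state[st[[ch]]]))
        names(counts) <- layout$chrom
        binned_track(counts, layout, bw, mk, cond, r)
      })
    }
    tracks[[cond]][["Mock"]] <- lapply(seq_len(config$n_reps), function(r) {
      counts <- lapply(layout$chrom, function(ch)
        stats::rpois(nb[[ch]], config$rate_low))
      names(counts) <- layout$chrom
      binned_track(counts, layout, bw, "Mock", cond, r)
    })
  }
  truth_seg <- lapply(all_states, function(st)
    structure(list(states = st, K = K, bin_width = bw, layout = layout),
              class = "Segmentation"))
  list(tracks = tracks, truth_seg = truth_seg,
       planted_transitions = planted)
}

#' Simulate expression counts, homoeolog structure and similarity tables
#'
#' Homoeolog pairs share a baseline mean (balanced); A-subgenome-unique
#' genes get their mean multiplied by \code{a_bias_factor}, planting the
#' subgenome expression bias in unique genes only. Between conditions,
#' genes with a planted promoter switch out of (into) the quiescent state
#' are up- (down-) regulated with probability \code{coupled_up_prob}; a
#' further random \code{de_fraction} of genes changes in a random
#' direction. Counts are negative binomial. The similarity tables plant
#' mutual best hits above the cuts for pairs, sub-threshold hits for unique
#' genes and non-reciprocal passing hits for the remainder.
#'
#' @param config a [simulation_config()].
#' @param genome a [simulate_genome()] result.
#' @param planted_transitions planted promoter switches from
#'   [simulate_state_tracks()] (may be \code{NULL}).
#' @return list with \code{counts} (gene x sample matrix),
#'   \code{conditions} (label per column), \code{hits_ad}, \code{hits_da},
#'   and \code{truth} (pairs, unique sets, DE directions).
#' @export
simulate_expression_and_homoeologs <- function(config, genome,
                                               planted_transitions = NULL) {
  set.seed(config$seed + 2L)
  genes <- genome$genes
  a_ids <- genes$gene_id[genes$subgenome == "A"]
  d_ids <- genes$gene_id[genes$subgenome == "D"]
  n_pairs <- round(config$homoeolog_fraction * min(length(a_ids),
                                                   length(d_ids)))
  pair_a <- sample(a_ids, n_pairs)
  pair_d <- sample(d_ids, n_pairs)
  n_uniq_a <- round(config$unique_fraction * length(a_ids))
  n_uniq_d <- round(config$unique_fraction * length(d_ids))
  uniq_a <- sample(setdiff(a_ids, pair_a), n_uniq_a)
  uniq_d <- sample(setdiff(d_ids, pair_d), n_uniq_d)
  other_a <- setdiff(a_ids, c(pair_a, uniq_a))
  other_d <- setdiff(d_ids, c(pair_d, uniq_d))

  # baseline means: pairs share a draw, everything else independent
  mu <- setNames(stats::rlnorm(nrow(genes), config$expr_meanlog,
                               config$expr_sdlog), genes$gene_id)
  mu[pair_d] <- mu[pair_a]
  mu[uniq_a] <- mu[uniq_a] * config$a_bias_factor

  # planted between-condition changes
  direction <- setNames(rep("none", nrow(genes)), genes$gene_id)
  if (!is.null(planted_transitions) && nrow(planted_transitions) > 0) {
    coupled <- planted_transitions$coupled != "none" &
      stats::runif(nrow(planted_transitions)) < config$coupled_up_prob
    direction[planted_transitions$gene_id[coupled]] <-
      planted_transitions$coupled[coupled]
  }
  free <- names(direction)[direction == "none"]
  n_de <- round(config$de_fraction * nrow(genes))
  extra <- sample(free, min(n_de, length(free)))
  direction[extra] <- sample(c("up", "down"), length(extra), replace = TRUE)

  mu2 <- mu
  mu2[direction == "up"] <- mu[direction == "up"] * config$de_effect
  mu2[direction == "down"] <- mu[direction == "down"] / config$de_effect
  size <- 1 / config$dispersion
  samples <- c(paste0(config$conditions[1], "_", seq_len(config$n_reps)),
               paste0(config$conditions[2], "_", seq_len(config$n_reps)))
  counts <- matrix(0L, nrow(genes), length(samples),
                   dimnames = list(genes$gene_id, samples))
  for (r in seq_len(config$n_reps)) {
    counts[, r] <- stats::rnbinom(nrow(genes), mu = mu, size = size)
    counts[, config$n_reps + r] <-
      stats::rnbinom(nrow(genes), mu = mu2, size = size)
  }
  conditions <- rep(config$conditions, each = config$n_reps)

  # similarity tables
  rlog10 <- function(n, lo, hi) 10^stats::runif(n, lo, hi)
  hit <- function(q, t, e, cov, id) data.frame(
    query_id = q, target_id = t, e_value = e, coverage = cov,
    identity = id, stringsAsFactors = FALSE)
  np <- length(pair_a)
  hits_ad <- hit(pair_a, pair_d, rlog10(np, -100, -20),
                 stats::runif(np, 60, 100), stats::runif(np, 55, 95))
  hits_da <- hit(pair_d, pair_a, rlog10(np, -100, -20),
                 stats::runif(np, 60, 100), stats::runif(np, 55, 95))
  if (length(other_a)) {
    decoy_t <- sample(pair_d, length(other_a), replace = TRUE)
    hits_ad <- rbind(hits_ad, hit(other_a, decoy_t,
                                  rlog10(length(other_a), -15, -6),
                                  stats::runif(length(other_a), 55, 90),
                                  stats::runif(length(other_a), 52, 80)))
  }
  if (length(other_d)) {
    decoy_t <- sample(pair_a, length(other_d), replace = TRUE)
    hits_da <- rbind(hits_da, hit(other_d, decoy_t,
                                  rlog10(length(other_d), -15, -6),
                                  stats::runif(length(other_d), 55, 90),
                                  stats::runif(length(other_d), 52, 80)))
  }
  if (length(uniq_a)) {
    hits_ad <- rbind(hits_ad, hit(uniq_a,
                                  sample(d_ids, length(uniq_a), TRUE),
                                  rlog10(length(uniq_a), -8, -2),
                                  stats::runif(length(uniq_a), 5, 45),
                                  stats::runif(length(uniq_a), 10, 45)))
  }
  if (length(uniq_d)) {
    hits_da <- rbind(hits_da, hit(uniq_d,
                                  sample(a_ids, length(uniq_d), TRUE),
                                  rlog10(length(uniq_d), -8, -2),
                                  stats::runif(length(uniq_d), 5, 45),
                                  stats::runif(length(uniq_d), 10, 45)))
  }
  truth <- list(
    pairs = data.frame(a_gene = sort(pair_a),
                       d_gene = pair_d[order(pair_a)],
                       stringsAsFactors = FALSE),
    a_unique = sort(uniq_a), d_unique = sort(uniq_d),
    a_other = sort(other_a), d_other = sort(other_d),
    de_direction = direction)
  list(counts = counts, conditions = conditions,
       hits_ad = hits_ad, hits_da = hits_da, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_state_tracks()] and
#' [simulate_expression_and_homoeologs()] with one configuration.
#'
#' @param config a [simulation_config()].
#' @return list combining all three results.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  genome <- simulate_genome(config)
  chrom <- simulate_state_tracks(config, genome)
  expr <- simulate_expression_and_homoeologs(config, genome,
                                             chrom$planted_transitions)
  c(genome, chrom, expr, list(config = config))
}

#' Sample binarized observations from a chromatin-state HMM
#'
#' Draws hidden state paths and Bernoulli mark observations directly from a
#' model — the generative counterpart of [baum_welch()], used for parameter
#' recovery studies.
#'
#' @param model a [chromatin_hmm()].
#' @param layout a [genome_layout()].
#' @param bin_width bin width (default 200).
#' @param seed RNG seed.
#' @return list with \code{data} (a [binary_matrix()]) and \code{states}
#'   (true per-chromosome paths).
#' @export
simulate_binary_from_hmm <- function(model, layout, bin_width = 200L,
                                     seed = 1L) {
  set.seed(seed)
  nb <- n_bins(layout, bin_width)
  states <- lapply(layout$chrom, function(ch)
    markov_path(nb[[ch]], model$transition, model$initial))
  names(states) <- layout$chrom
  M <- length(model$marks)
  binarized <- lapply(setNames(model$marks, model$marks), function(mk) {
    lapply(states, function(s)
      as.integer(stats::runif(length(s)) < model$emission[s, mk]))
  })
  list(data = binary_matrix(binarized, layout, bin_width), states = states)
}
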