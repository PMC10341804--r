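#' Pipeline configuration
#'
#' Named thresholds for every stage, defaulting to the study's settings:
#' 200-bp bins, binarization p 1e-4, six states, peak cutoffs p < 1e-10 and
#' fold change > 5, 500-bp promoters, DE at FDR <= 0.05 and |log2FC| > 1,
#' RBH cuts E < 1e-5 with coverage and identity >= 50%, five gene clusters.
#' The default configuration is therefore the zero-edit "paper mode".
#'
#' @param bin_width chromatin bin width in bases.
#' @param binarize_p binarization Poisson tail threshold.
#' @param K number of chromatin states.
#' @param peak_p,peak_fc broad-peak cutoffs.
#' @param promoter_len promoter length in bases upstream of the TSS.
#' @param de_alpha,de_lfc DE thresholds (FDR, |log2FC|).
#' @param rbh_e,rbh_cov,rbh_id RBH cuts.
#' @param kmeans_k gene clusters.
#' @param seed master seed.
#' @param n_restarts,em_tol,em_max_iter HMM learning controls.
#' @param sim a [simulation_config()] used by the \code{simulate} stage.
#' @return a \code{PipelineConfig} list.
#' @export
pipeline_config <- function(bin_width = 200L, binarize_p = 1e-4, K = 6L,
                            peak_p = 1e-10, peak_fc = 5,
                            promoter_len = 500L,
                            de_alpha = 0.05, de_lfc = 1,
                            rbh_e = 1e-5, rbh_cov = 50, rbh_id = 50,
                            kmeans_k = 5L, seed = 1L,
                            n_restarts = 3L, em_tol = 1e-4,
                            em_max_iter = 100L,
                            sim = simulation_config(seed = seed)) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(bin_width > 0, binarize_p > 0, K >= 1, peak_p > 0,
                      peak_fc > 0, promoter_len > 0, de_alpha > 0,
                      de_lfc > 0, rbh_e > 0, rbh_cov > 0, rbh_id > 0,
                      kmeans_k >= 1))
  structure(cfg, class = "PipelineConfig")
}

stage_order <- c("simulate", "binarize", "learn", "segment", "annotate",
                 "assign", "de", "transitions", "bias", "cluster", "report")

read_layout_tsv <- function(path) {
  d <- data.table::fread(path)
  genome_layout(d$chrom, d$length, d$subgenome)
}

# rebuild a Segmentation from its dense interval BED
segmentation_from_bed <- function(path, layout, bin_width, K) {
  iv <- read_bed(path)
  states <- lapply(layout$chrom, function(ch) {
    v <- integer(n_bins(layout, bin_width)[[ch]])
    d <- iv[iv$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      b0 <- d$start[i] %/% bin_width + 1L
      b1 <- (d$end[i] - 1L) %/% bin_width + 1L
      v[b0:b1] <- as.integer(sub("^S", "", d$name[i]))
    }
    v
  })
  names(states) <- layout$chrom
  structure(list(states = states, K = K, bin_width = bin_width,
                 layout = layout), class = "Segmentation")
}

write_manifest <- function(outdir, stage, config, inputs, outputs) {
  manifest <- list(
    stage = stage,
    version = as.character(utils::packageVersion("allostate")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs) &
                                            !dir.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs) &
                                              !dir.exists(outputs)])))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

need <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input(s): ", paste(missing, collapse = ", "),
         " - run the earlier stage first")
  }
  paths
}

track_path <- function(outdir, cond, mark, rep) {
  file.path(outdir, "tracks", sprintf("%s_%s_rep%d.bedGraph", cond, mark, rep))
}

read_track <- function(path, layout, bin_width, mark, cond, rep) {
  sig <- read_bedgraph(path, layout, bin_width)
  binned_track(lapply(sig, as.integer), layout, bin_width, mark, cond, rep)
}

#' Run one pipeline stage
#'
#' Stages (in order): \code{simulate} (write all synthetic inputs and truth
#' tables), \code{binarize}, \code{learn}, \code{segment}, \code{annotate},
#' \code{assign}, \code{de}, \code{transitions}, \code{bias},
#' \code{cluster}, \code{report}. Each stage reads its inputs from
#' \code{outdir}, writes its outputs there and records a JSON manifest with
#' the config snapshot, seed and input/output checksums; deterministic
#' stages reproduce their outputs byte-identically on rerun.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @param outdir working directory for the pipeline run.
#' @return stage-specific result, invisibly.
#' @export
run_stage <- function(name, config = pipeline_config(), outdir) {
  name <- match.arg(name, stage_order)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marks <- colnames(config$sim$emission)
  conds <- config$sim$conditions
  layout_path <- file.path(outdir, "layout.tsv")
  result <- switch(
    name,
    simulate = {
      sim <- simulate_dataset(config$sim)
      data.table::fwrite(as.data.frame(unclass(sim$layout)), layout_path,
                         sep = "\t")
      write_gff3_genes(sim$genes, sim$exons, file.path(outdir, "genes.gff3"))
      te <- sim$tes
      te$name <- te$te_class
      write_bed(te, file.path(outdir, "tes.bed"))
      dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
      for (cond in conds) for (mk in c(marks, "Mock")) {
        for (r in seq_len(config$sim$n_reps)) {
          tr <- sim$tracks[[cond]][[mk]][[r]]
          sig <- lapply(tr$counts, as.numeric)
          attr(sig, "bin_width") <- tr$bin_width
          attr(sig, "layout") <- tr$layout
          write_bedgraph(sig, track_path(outdir, cond, mk, r))
        }
      }
      counts <- data.table::as.data.table(sim$counts, keep.rownames = "gene_id")
      data.table::fwrite(counts, file.path(outdir, "counts.tsv"), sep = "\t")
      data.table::fwrite(sim$hits_ad, file.path(outdir, "hits_ad.tsv"),
                         sep = "\t")
      data.table::fwrite(sim$hits_da, file.path(outdir, "hits_da.tsv"),
                         sep = "\t")
      dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
      write_segmentation_bed(sim$truth_seg[[1]],
                             file.path(outdir, "truth",
                                       paste0("segmentation_", conds[1], ".bed")))
      write_segmentation_bed(sim$truth_seg[[2]],
                             file.path(outdir, "truth",
                                       paste0("segmentation_", conds[2], ".bed")))
      data.table::fwrite(sim$planted_transitions,
                         file.path(outdir, "truth", "planted_transitions.tsv"),
                         sep = "\t")
      data.table::fwrite(sim$truth$pairs,
                         file.path(outdir, "truth", "pairs.tsv"), sep = "\t")
      for (nm in c("a_unique", "d_unique", "a_other", "d_other")) {
        writeLines(sim$truth[[nm]],
                   file.path(outdir, "truth", paste0(nm, ".txt")))
      }
      data.table::fwrite(
        data.frame(gene_id = names(sim$truth$de_direction),
                   direction = sim$truth$de_direction),
        file.path(outdir, "truth", "de_direction.tsv"), sep = "\t")
      sim
    },
    binarize = {
      need(layout_path)
      layout <- read_layout_tsv(layout_path)
      for (cond in conds) {
        paths <- c(vapply(marks, function(mk)
          track_path(outdir, cond, mk, 1L), character(1)))
        need(paths)
        mock <- pool_tracks(lapply(seq_len(config$sim$n_reps), function(r)
          read_track(track_path(outdir, cond, "Mock", r), layout,
                     config$bin_width, "Mock", cond, r)))
        binarized <- lapply(setNames(marks, marks), function(mk) {
          chip <- pool_tracks(lapply(seq_len(config$sim$n_reps), function(r)
            read_track(track_path(outdir, cond, mk, r), layout,
                       config$bin_width, mk, cond, r)))
          binarize(chip, mock, config$binarize_p)
        })
        bm <- binary_matrix(binarized, layout, config$bin_width)
        write_binary_files(bm, file.path(outdir, paste0("binary_", cond)),
                           genome = cond)
      }
      invisible(NULL)
    },
    learn = {
      layout <- read_layout_tsv(need(layout_path))
      paths <- need(list.files(file.path(outdir, paste0("binary_", conds[1])),
                               full.names = TRUE))
      bm <- read_binary_files(paths, layout, config$bin_width)
      model <- baum_welch(bm, K = config$K, n_restarts = config$n_restarts,
                          seed = config$seed, tol = config$em_tol,
                          max_iter = config$em_max_iter)
      model <- relabel_states(model)$model
      write_hmm_json(model, file.path(outdir, "model.json"))
      model
    },
    segment = {
      layout <- read_layout_tsv(need(layout_path))
      model <- read_hmm_json(need(file.path(outdir, "model.json")))
      for (cond in conds) {
        paths <- need(list.files(file.path(outdir, paste0("binary_", cond)),
                                 full.names = TRUE))
        bm <- read_binary_files(paths, layout, config$bin_width)
        seg <- decode(model, bm)
        write_segmentation_bed(seg, file.path(outdir,
                                              paste0("segmentation_", cond, ".bed")))
        cov <- state_coverage(seg, layout, by_subgenome = TRUE)
        data.table::fwrite(cov, file.path(outdir,
                                          paste0("state_coverage_", cond, ".tsv")),
                           sep = "\t")
      }
      invisible(NULL)
    },
    annotate = {
      layout <- read_layout_tsv(need(layout_path))
      gm <- read_gff3_genes(need(file.path(outdir, "genes.gff3")))
      te <- read_bed(need(file.path(outdir, "tes.bed")))
      te$te_class <- te$name
      seg <- segmentation_from_bed(
        need(file.path(outdir, paste0("segmentation_", conds[1], ".bed"))),
        layout, config$bin_width, config$K)
      emap <- build_element_map(gm$genes, gm$exons, layout,
                                config$promoter_len)
      data.table::fwrite(emap, file.path(outdir, "element_map.tsv"),
                         sep = "\t")
      se <- state_by_element(seg, emap)
      st <- state_by_te(seg, te)
      write_matrix_tsv <- function(m, path) {
        data.table::fwrite(data.table::as.data.table(as.data.frame(m),
                                                     keep.rownames = "state"),
                           path, sep = "\t")
      }
      write_matrix_tsv(se$by_state, file.path(outdir, "state_by_element.tsv"))
      write_matrix_tsv(se$by_element, file.path(outdir, "element_by_state.tsv"))
      write_matrix_tsv(st$bases_by_state, file.path(outdir, "state_by_te.tsv"))
      list(elements = se, tes = st)
    },
    assign = {
      layout <- read_layout_tsv(need(layout_path))
      gm <- read_gff3_genes(need(file.path(outdir, "genes.gff3")))
      out <- list()
      for (cond in conds) {
        seg <- segmentation_from_bed(
          need(file.path(outdir, paste0("segmentation_", cond, ".bed"))),
          layout, config$bin_width, config$K)
        asg <- assign_gene_state(gm$genes, seg, config$promoter_len, cond)
        data.table::fwrite(asg, file.path(outdir,
                                          paste0("gene_states_", cond, ".tsv")),
                           sep = "\t")
        out[[cond]] <- asg
      }
      out
    },
    de = {
      counts <- as.matrix(data.table::fread(need(file.path(outdir, "counts.tsv"))),
                          rownames = "gene_id")
      cond_of <- sub("_[0-9]+$", "", colnames(counts))
      de <- nb_de_test(counts, cond_of, conds[1], conds[2],
                       alpha = config$de_alpha, lfc_cut = config$de_lfc)
      data.table::fwrite(de, file.path(outdir, "de.tsv"), sep = "\t")
      de
    },
    transitions = {
      asg <- lapply(conds, function(cond)
        as.data.frame(data.table::fread(
          need(file.path(outdir, paste0("gene_states_", cond, ".tsv"))))))
      de <- as.data.frame(data.table::fread(need(file.path(outdir, "de.tsv"))))
      ledger <- build_transition_ledger(asg[[1]], asg[[2]], K = config$K)
      data.table::fwrite(ledger$ledger, file.path(outdir, "transitions.tsv"),
                         sep = "\t")
      data.table::fwrite(
        data.table::as.data.table(as.data.frame(ledger$matrix),
                                  keep.rownames = "state_from"),
        file.path(outdir, "transition_matrix.tsv"), sep = "\t")
      enr <- rbind(transition_deg_enrichment(ledger, de, "any"),
                   transition_deg_enrichment(ledger, de, "up"),
                   transition_deg_enrichment(ledger, de, "down"))
      data.table::fwrite(enr, file.path(outdir, "transition_enrichment.tsv"),
                         sep = "\t")
      list(ledger = ledger, enrichment = enr)
    },
    bias = {
      gm <- read_gff3_genes(need(file.path(outdir, "genes.gff3")))
      hits_ad <- as.data.frame(data.table::fread(need(file.path(outdir, "hits_ad.tsv"))))
      hits_da <- as.data.frame(data.table::fread(need(file.path(outdir, "hits_da.tsv"))))
      counts <- as.matrix(data.table::fread(need(file.path(outdir, "counts.tsv"))),
                          rownames = "gene_id")
      cond_of <- sub("_[0-9]+$", "", colnames(counts))
      rbh <- reciprocal_best_hits(
        hits_ad, hits_da,
        a_genes = gm$genes$gene_id[gm$genes$subgenome == "A"],
        d_genes = gm$genes$gene_id[gm$genes$subgenome == "D"],
        e_cut = config$rbh_e, cov_cut = config$rbh_cov,
        id_cut = config$rbh_id)
      bias <- categorize_bias(rbh, counts[, cond_of == conds[1], drop = FALSE],
                              alpha = config$de_alpha,
                              lfc_cut = config$de_lfc)
      data.table::fwrite(rbh$pairs, file.path(outdir, "rbh_pairs.tsv"),
                         sep = "\t")
      data.table::fwrite(bias, file.path(outdir, "bias_categories.tsv"),
                         sep = "\t")
      writeLines(rbh$a_unique, file.path(outdir, "a_unique.txt"))
      writeLines(rbh$d_unique, file.path(outdir, "d_unique.txt"))
      list(rbh = rbh, bias = bias)
    },
    cluster = {
      layout <- read_layout_tsv(need(layout_path))
      gm <- read_gff3_genes(need(file.path(outdir, "genes.gff3")))
      signals <- lapply(setNames(marks, marks), function(mk) {
        tr <- pool_tracks(lapply(seq_len(config$sim$n_reps), function(r)
          read_track(need(track_path(outdir, conds[1], mk, r)), layout,
                     config$bin_width, mk, conds[1], r)))
        rpkm_normalize(tr)
      })
      histone <- setdiff(marks, "DNase")
      sigmat <- gene_signal_matrix(signals[histone], gm$genes)
      cl <- kmeans_gene_clusters(sigmat, k = config$kmeans_k,
                                 seed = config$seed)
      data.table::fwrite(data.frame(gene_id = names(cl$labels),
                                    cluster = paste0("C", cl$labels)),
                         file.path(outdir, "gene_clusters.tsv"), sep = "\t")
      enr <- newgene_cluster_enrichment(
        cl$labels, gm$genes$gene_id[gm$genes$is_new_gene])
      data.table::fwrite(enr, file.path(outdir, "newgene_enrichment.tsv"),
                         sep = "\t")
      list(clusters = cl, enrichment = enr)
    },
    report = {
      layout <- read_layout_tsv(need(layout_path))
      cov <- data.table::fread(need(file.path(outdir,
                                              paste0("state_coverage_", conds[1], ".tsv"))))
      led <- data.table::fread(need(file.path(outdir, "transitions.tsv")))
      de <- data.table::fread(need(file.path(outdir, "de.tsv")))
      bias <- data.table::fread(need(file.path(outdir, "bias_categories.tsv")))
      rep <- list(
        genome_bases = sum(layout$length),
        top_state_fraction = max(cov$fraction[cov$scope == "genome"]),
        transition_gene_fraction = mean(led$state_from != led$state_to),
        n_deg = sum(de$call != "ns"),
        deg_fraction = mean(de$call != "ns"),
        biased_pair_percent =
          100 * mean(bias$category != "A=D"))
      jsonlite::write_json(rep, file.path(outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rep
    })
  inputs <- layout_path
  outputs <- list.files(outdir, full.names = TRUE, recursive = FALSE)
  outputs <- outputs[!grepl("^manifest_", basename(outputs))]
  write_manifest(outdir, name, config, inputs, outputs)
  invisible(result)
}

#' Run the full pipeline on synthetic data
#'
#' Convenience wrapper running every stage in order.
#'
#' @param config a [pipeline_config()].
#' @param outdir working directory.
#' @return the report list from the final stage.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  for (st in stage_order) run_stage(st, config, outdir)
  jsonlite::read_json(file.path(outdir, "report.json"), simplifyVector = TRUE)
}
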