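# End-to-end orchestration: compose the simulation, normalization, DE, length
# binning, enrichment and reproducibility stages from one configuration and
# write a machine-readable report bundle. File outputs carry no timestamps so
# identical config + seed reproduces the bundle byte for byte.

.default_params <- list(
  min_count = 20, min_replicates = NULL, alpha = 0.05, bin_size = 500,
  tmm_threshold = 1, direction_mode = "all_genes", n_perm = 10000,
  gsea_min_size = 1, gsea_max_size = 5000
)

.pipe_log <- function(stage, seed, ...) {
  message(sprintf("[%s] seed=%s %s", stage, seed, paste0(...)))
}

.write_tsv <- function(d, path) {
  write.table(d, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

.bins_tsv <- function(bins) {
  data.frame(
    bin_index = bins$bin_index, mean_length_bp = bins$mean_length_bp,
    n_up = bins$n_up, n_down = bins$n_down, n_total = bins$n_total,
    up_ratio = bins$up_ratio
  )
}

.fit_json <- function(fit) {
  fit[c("slope", "intercept", "pearson_r", "t_stat", "df", "pvalue", "n_bins")]
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes simulate/load, filter, normalize, differential expression
#' (internal Wald surrogate or ingested external tables), length-bin
#' analysis, gene-set enrichment, and — when at least two cohorts are present
#' — cross-cohort reproducibility, writing every stage's TSV/JSON outputs and
#' a run manifest into `out_dir`. Outputs are byte-identical across runs with
#' the same configuration and seed. A stage failure writes a `FAILED` marker
#' naming the stage and re-raises the error; outputs of completed stages are
#' retained.
#'
#' @param config A configuration list or path to a YAML file. Recognized
#'   top-level keys: `seed`, `out_dir`, `params` (see Details), and either
#'   `simulate` (keys `n_genes`, `de_fraction`, `gltd_slope`, `effect_scale`,
#'   `cohorts` as a list of `name`/`n_per_group`, optional `gene_sets` with
#'   `n_sets`/`n_enriched`/`set_size`/`enrichment_bias`) or `inputs` (per
#'   cohort `name`, `counts`, `metadata`, optional `de`; plus `annotation`
#'   TSV or `gtf`, optional `gmt`).
#' @param out_dir Optional override of `config$out_dir`.
#' @details `params` keys and defaults: `min_count` 20, `min_replicates`
#'   half the smallest group, `alpha` 0.05, `bin_size` 500, `tmm_threshold`
#'   1, `direction_mode` `"all_genes"`, `n_perm` 10000, `gsea_min_size` 1,
#'   `gsea_max_size` 5000.
#' @return Invisibly, a list with per-cohort results (`de`, `bins`, `fit`,
#'   `enrichment`), the cross-cohort block, and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- modifyList(.default_params, config$params %||% list())
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # the config echo omits the output location so that two runs of the same
  # analysis into different directories produce byte-identical bundles
  config_echo <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "gltdseq",
    version = as.character(packageVersion("gltdseq")),
    seed = seed, config = config_echo, stages = list()
  )
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(
      c(paste("FAILED at stage:", stage), conditionMessage(e)),
      file.path(out_dir, "FAILED")
    )
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      call. = FALSE
    )
  }
  result <- tryCatch(
    {
      # ---- stage: data (simulate or load) ----
      stage <- "data"
      cohorts <- list()
      annotation <- NULL
      sets <- NULL
      truth <- NULL
      if (!is.null(config$simulate)) {
        sim <- config$simulate
        universe <- NULL
        for (i in seq_along(sim$cohorts)) {
          cc <- sim$cohorts[[i]]
          cfg <- sim_config(
            n_genes = sim$n_genes %||% 12000,
            n_per_group = cc$n_per_group %||% 6,
            de_fraction = sim$de_fraction %||% 0.35,
            gltd_slope = sim$gltd_slope %||% 1.0,
            effect_scale = sim$effect_scale %||% 0.2,
            seed = seed
          )
          sc <- simulate_cohort(cfg,
            cohort = cc$name %||% paste0("cohort", i),
            universe = universe, cohort_index = i - 1L
          )
          universe <- sc$universe
          annotation <- sc$annotation
          cohorts[[cc$name %||% paste0("cohort", i)]] <- list(
            counts = sc$counts, de_external = NULL
          )
          truth <- sc$effects
        }
        if (!is.null(sim$gene_sets)) {
          gs <- sim$gene_sets
          sets <- generate_gene_sets(universe, truth,
            n_sets = gs$n_sets %||% 9, n_enriched = gs$n_enriched %||% 3,
            set_size = gs$set_size %||% 100,
            enrichment_bias = gs$enrichment_bias %||% 3,
            seed = seed
          )
          write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
        }
        .pipe_log(stage, seed, sprintf(
          "simulated %d cohort(s), %d genes",
          length(cohorts), nrow(annotation)
        ))
      } else if (!is.null(config$inputs)) {
        ins <- config$inputs
        for (cc in ins$cohorts) {
          cm <- read_counts(cc$counts, cc$metadata)
          de_ext <- if (!is.null(cc$de)) read_de_table(cc$de, alpha = params$alpha)
          cohorts[[cc$name]] <- list(counts = cm, de_external = de_ext)
        }
        annotation <- if (!is.null(ins$gtf)) {
          gene_lengths_from_gtf(ins$gtf)
        } else {
          read_gene_lengths(ins$annotation)
        }
        if (!is.null(ins$gmt)) sets <- read_gmt(ins$gmt)
        .pipe_log(stage, seed, sprintf(
          "loaded %d cohort(s): %s", length(cohorts),
          paste(names(cohorts), collapse = ", ")
        ))
      } else {
        stop("config needs either a `simulate` or an `inputs` block")
      }
      manifest$stages$data <- list(
        n_cohorts = length(cohorts), n_genes = nrow(annotation),
        n_gene_sets = if (is.null(sets)) 0L else length(sets)
      )

      # ---- stage: per-cohort analysis ----
      stage <- "gltd"
      per_cohort <- list()
      for (nm in names(cohorts)) {
        res <- gltd_analysis(
          cohorts[[nm]]$counts, annotation,
          min_replicates = params$min_replicates,
          min_count = params$min_count,
          tmm_threshold = params$tmm_threshold,
          bin_size = params$bin_size, alpha = params$alpha,
          mode = params$direction_mode,
          de = cohorts[[nm]]$de_external
        )
        write_de_table(res$de, file.path(out_dir, sprintf("de_%s.tsv", nm)))
        .write_tsv(.bins_tsv(res$bins), file.path(out_dir, sprintf("bins_%s.tsv", nm)))
        per_cohort[[nm]] <- res
        .pipe_log(stage, seed, sprintf(
          "%s: %d expressed, %d binned, slope=%.4f (p=%.3g), %d DEGs",
          nm, length(res$expressed), length(res$universe),
          res$fit$slope, res$fit$pvalue, sum(res$de$significant)
        ))
        manifest$stages[[paste0("gltd_", nm)]] <- list(
          n_expressed = length(res$expressed),
          n_bin_universe = length(res$universe),
          n_bins = res$fit$n_bins,
          n_significant = sum(res$de$significant)
        )
      }

      # ---- stage: enrichment ----
      stage <- "enrichment"
      enrichment <- list()
      if (!is.null(sets)) {
        for (nm in names(per_cohort)) {
          ranked <- rank_genes(per_cohort[[nm]]$de)
          enr <- gsea(ranked, sets,
            n_perm = params$n_perm,
            min_size = params$gsea_min_size, max_size = params$gsea_max_size,
            seed = seed
          )
          write_enrichment(enr, file.path(out_dir, sprintf("enrichment_%s.tsv", nm)))
          enrichment[[nm]] <- enr
          .pipe_log(stage, seed, sprintf(
            "%s: %d sets, %d at padj<%.2f", nm, nrow(enr),
            sum(enr$padj < params$alpha), params$alpha
          ))
        }
        manifest$stages$enrichment <- list(n_sets = length(sets))
      } else {
        manifest$stages$enrichment <- "skipped (no gene sets)"
        .pipe_log(stage, seed, "skipped (no gene sets)")
      }

      # ---- stage: cross-cohort ----
      stage <- "reproducibility"
      cross <- NULL
      if (length(per_cohort) >= 2L) {
        nms <- names(per_cohort)[1:2]
        a <- per_cohort[[nms[1L]]]
        b <- per_cohort[[nms[2L]]]
        inter <- cohort_interaction_regression(a$bins, b$bins)
        cors <- profile_correlations(
          cohorts[[nms[1L]]]$counts, cohorts[[nms[2L]]]$counts
        )
        dircon <- tryCatch(
          directionality_consistency(a$de, b$de),
          error = function(e) list(error = conditionMessage(e))
        )
        # pooled analysis over the two cohorts' shared genes
        common <- intersect(
          rownames(cohorts[[nms[1L]]]$counts$counts),
          rownames(cohorts[[nms[2L]]]$counts$counts)
        )
        pooled_cm <- count_matrix(
          cbind(
            cohorts[[nms[1L]]]$counts$counts[common, , drop = FALSE],
            cohorts[[nms[2L]]]$counts$counts[common, , drop = FALSE]
          ),
          rbind(
            cohorts[[nms[1L]]]$counts$sample_meta,
            cohorts[[nms[2L]]]$counts$sample_meta
          )
        )
        pooled <- gltd_analysis(pooled_cm, annotation,
          min_replicates = params$min_replicates,
          min_count = params$min_count,
          tmm_threshold = params$tmm_threshold,
          bin_size = params$bin_size, alpha = params$alpha,
          mode = params$direction_mode
        )
        write_de_table(pooled$de, file.path(out_dir, "de_pooled.tsv"))
        deg_sets <- list()
        deg_sets[[nms[1L]]] <- a$de$gene_id[a$de$significant]
        deg_sets[[nms[2L]]] <- b$de$gene_id[b$de$significant]
        deg_sets$pooled <- pooled$de$gene_id[pooled$de$significant]
        overlap <- overlap_analysis(deg_sets, pooled = "pooled")
        ov <- overlap[, c("region", "count")]
        .write_tsv(ov, file.path(out_dir, "overlap.tsv"))
        cross <- list(
          interaction = inter, correlations = cors,
          directionality = dircon, pooled = pooled, overlap = overlap
        )
        .write_json(list(
          correlations = unclass(cors),
          directionality = dircon,
          interaction = list(
            f_stat = inter$f_stat, df = inter$df, pvalue = inter$pvalue,
            pooled = inter$pooled
          ),
          lost_by_pooling = attr(overlap, "lost_by_pooling")
        ), file.path(out_dir, "repro.json"))
        .pipe_log(stage, seed, sprintf(
          "between-cohort r=%.3f, interaction F=%.2f (p=%.3g)",
          cors$between_mean, inter$f_stat, inter$pvalue
        ))
        manifest$stages$reproducibility <- list(
          n_shared_genes = cors$n_genes,
          n_pooled_significant = sum(pooled$de$significant)
        )
      } else {
        manifest$stages$reproducibility <- "skipped (single cohort)"
        .pipe_log(stage, seed, "skipped (single cohort)")
      }

      # ---- stage: report ----
      stage <- "report"
      fits <- lapply(per_cohort, function(r) .fit_json(r$fit))
      if (!is.null(cross)) {
        fits$interaction <- list(
          f_stat = cross$interaction$f_stat, df = cross$interaction$df,
          pvalue = cross$interaction$pvalue, pooled = cross$interaction$pooled
        )
      }
      .write_json(fits, file.path(out_dir, "fits.json"))
      files <- sort(setdiff(list.files(out_dir), c("manifest.json", "FAILED")))
      manifest$files <- as.list(
        tools::md5sum(file.path(out_dir, files))
      )
      names(manifest$files) <- files
      .write_json(manifest, file.path(out_dir, "manifest.json"))
      .pipe_log(stage, seed, sprintf("bundle written to %s", out_dir))
      invisible(list(
        cohorts = per_cohort, enrichment = enrichment, cross = cross,
        manifest = manifest, out_dir = out_dir
      ))
    },
    error = on_fail
  )
  result
}

#' Calibration and power study over a simulation grid
#'
#' For each grid row, simulates `replicates` cohorts and records the
#' operating characteristics of the length-decline analysis: the rejection
#' rate and mean estimate of the up-ratio-versus-length slope, the gene-level
#' type-I rate of the Wald test over true-null genes, and its power over
#' truly affected genes.
#'
#' @param grid `data.frame` whose columns override [sim_config()] fields
#'   (`n_genes`, `n_per_group`, `de_fraction`, `gltd_slope`, `effect_scale`);
#'   defaults to a slope sweep `c(0, 0.5, 1, 1.5)` at 6000 genes.
#' @param replicates Simulated cohorts per grid row, >= 1.
#' @param seed Master seed; replicate r of row g uses an independent
#'   substream.
#' @param alpha Significance level, default 0.05.
#' @return `data.frame`: one row per grid point with columns
#'   `slope_rejection_rate`, `mean_slope`, `mean_slope_p`, `de_type1`,
#'   `de_power`, `n_replicates`.
#' @export
run_simulation_study <- function(grid = NULL, replicates = 20, seed = 1L,
                                 alpha = 0.05) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(grid)) {
    grid <- data.frame(gltd_slope = c(0, 0.5, 1, 1.5), n_genes = 6000)
  }
  base <- sim_config()
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg_args <- as.list(grid[g, , drop = FALSE])
    cfg_args <- cfg_args[names(cfg_args) %in% names(base)]
    stats <- vapply(seq_len(replicates), function(r) {
      cfg <- do.call(sim_config, c(cfg_args, list(
        seed = substream_seed(seed, "study", index = (g - 1L) * replicates + r)
      )))
      sim <- simulate_cohort(cfg)
      res <- gltd_analysis(sim$counts, sim$annotation, alpha = alpha)
      truth <- sim$effects[match(res$de$gene_id, sim$effects$gene_id), ]
      null_p <- res$de$pvalue[!truth$is_de]
      de_p <- res$de$padj[truth$is_de]
      c(
        reject = as.numeric(res$fit$pvalue < alpha),
        slope = res$fit$slope,
        slope_p = res$fit$pvalue,
        type1 = mean(null_p < alpha),
        power = if (length(de_p)) mean(de_p < alpha) else NA_real_
      )
    }, numeric(5L))
    data.frame(
      grid[g, , drop = FALSE],
      slope_rejection_rate = mean(stats["reject", ]),
      mean_slope = mean(stats["slope", ]),
      mean_slope_p = mean(stats["slope_p", ]),
      de_type1 = mean(stats["type1", ]),
      de_power = mean(stats["power", ], na.rm = TRUE),
      n_replicates = replicates,
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
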