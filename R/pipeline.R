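#' Run the full occurrence-to-drivers analysis from one config
#'
#' Orchestrates read/simulate -> bin -> partition -> raw diversity ->
#' SQS -> turnover rates -> driver models from a single declarative
#' configuration (a named list, or the path of a YAML file). All
#' randomness flows from the top-level `seed`; rerunning the same config
#' is bit-identical. Any stage error aborts with a stage-labelled message
#' and removes partial outputs.
#'
#' Config keys: `seed`; `output_dir`; `input` (either
#' `occurrences:` a CSV path, or `simulate:` with `n_bins`,
#' `initial_richness`, `lambda`, `mu`, `collections_per_bin`,
#' `occ_per_collection`); `bins` (`"stage"`, `"tenmyr"`, a CSV path, or
#' omitted to use the synthetic scheme); `partitions` (list of
#' `{by, value, label}`; empty = whole table, label `"all"`); `sqs`
#' (passed to [sqs_config()]); `rates` (subset of `"foote"`,
#' `"threetimer"`); `drivers` (optional long-format CSV path, see
#' [read_driver_series()]).
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, a list of written file paths plus the in-memory
#'   results (`curves`, `rates`, `driver_models`, `correlations`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration error: config file not found: ", config,
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir
  if (is.null(out_dir)) {
    stop("configuration error: output_dir is required", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    write_curve_csv(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- input stage -----------------------------------------------------
  scheme <- NULL
  occs <- stage("input", {
    if (!is.null(config$input$occurrences)) {
      path <- config$input$occurrences
      if (!file.exists(path)) {
        stop("configuration error: occurrence file not found: ", path)
      }
      read_occurrence_table(path,
                            config$column_map %||% default_column_map())
    } else if (!is.null(config$input$simulate)) {
      sim <- config$input$simulate
      world <- simulate_true_world(
        n_bins = sim$n_bins %||% 12L,
        initial_richness = sim$initial_richness %||% 50L,
        lambda = sim$lambda %||% 0.1,
        mu = sim$mu %||% 0.1,
        seed = seed
      )
      regime <- sampling_regime(
        collections_per_bin = sim$collections_per_bin %||% 20L,
        occ_per_collection = sim$occ_per_collection %||% 3
      )
      rec <- simulate_fossil_record(world, regime, seed = seed + 1L)
      scheme <- attr(rec, "scheme")
      rec
    } else {
      stop("configuration error: input needs 'occurrences' or 'simulate'")
    }
  })

  # --- binning stage ---------------------------------------------------
  binned <- stage("binning", {
    sel <- config$bins
    if (!is.null(sel)) {
      scheme <- switch(sel,
        stage = jk_stage_bins(),
        tenmyr = jk_tenmyr_bins(),
        read_bin_scheme(sel))
    }
    if (is.null(scheme)) {
      stop("configuration error: no bin scheme (set 'bins' or simulate input)")
    }
    assign_to_bins(occs, scheme)
  })

  # --- partitions ------------------------------------------------------
  parts <- config$partitions
  if (is.null(parts) || !length(parts)) {
    parts <- list(list(by = NULL, value = NULL, label = "all"))
  }
  sqs_cfg <- do.call(sqs_config, utils::modifyList(
    list(seed = seed), as.list(config$sqs %||% list())))
  methods <- config$rates %||% c("foote", "threetimer")

  curves <- list()
  rates <- list()
  sqs_curves <- list()
  for (p in parts) {
    label <- p$label %||% paste0(p$by, "_", p$value)
    sub <- stage(paste0("partition:", label), {
      if (is.null(p$by)) binned else partition_occurrences(binned, p$by, p$value)
    })
    curves[[label]] <- stage(paste0("diversity:", label), {
      tde <- raw_taxonomic_diversity(sub, label = paste0("TDE_", label))
      emit(tde, sprintf("tde_%s.csv", label))
      tde
    })
    sqs_curves[[label]] <- stage(paste0("sqs:", label), {
      est <- sqs_estimate(sub, sqs_cfg, label = paste0("SQS_", label))
      emit(est, sprintf("sqs_%s.csv", label))
      est
    })
    rates[[label]] <- stage(paste0("rates:", label), {
      if (nrow(.assigned(sub)) == 0L) return(NULL)
      rr <- compile_taxon_ranges(sub)
      out <- list()
      if ("foote" %in% methods) {
        out$foote <- foote_rates(rr)
        emit(out$foote, sprintf("rates_foote_%s.csv", label))
      }
      if ("threetimer" %in% methods) {
        out$threetimer <- three_timer_rates(rr)
        emit(out$threetimer, sprintf("rates_threetimer_%s.csv", label))
      }
      out
    })
  }

  # --- drivers ---------------------------------------------------------
  driver_models <- NULL
  correlations <- NULL
  if (!is.null(config$drivers)) {
    driver_models <- stage("drivers", {
      series <- read_driver_series(config$drivers)
      rebinned <- lapply(series, rebin_series, scheme = scheme)
      drv <- lapply(rebinned, `[[`, "value")
      all_models <- list()
      all_cors <- list()
      for (label in names(sqs_curves)) {
        resp <- sqs_curves[[label]]
        if (sum(!is.na(resp$mean)) < 4L) next
        mm <- compare_driver_models(resp, drv)
        mm <- cbind(group = label, mm)
        cc <- correlation_tests(resp, drv, family_label = label)
        cc <- cbind(group = label, cc)
        all_models[[label]] <- mm
        all_cors[[label]] <- cc
      }
      if (length(all_models)) {
        dm <- do.call(rbind, all_models)
        correlations <- do.call(rbind, all_cors)
        emit(dm, "driver_models.csv")
        emit(correlations, "driver_correlations.csv")
        dm
      } else {
        NULL
      }
    })
  }

  # --- manifest --------------------------------------------------------
  stage("manifest", {
    cfg_file <- tempfile(fileext = ".yaml")
    on.exit(unlink(cfg_file))
    yaml::write_yaml(config, cfg_file)
    manifest <- list(
      package = "quorumdiv",
      version = as.character(utils::packageVersion("quorumdiv")),
      seed = seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      n_occurrences = nrow(occs),
      n_assigned = nrow(.assigned(binned)),
      outputs = basename(written)
    )
    path <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, path)
    written <<- c(written, path)
  })

  invisible(list(files = written, curves = curves, sqs = sqs_curves,
                 rates = rates, driver_models = driver_models,
                 correlations = correlations))
}
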