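# Run configuration and provenance capture: every experiment is described by
# a serialisable config (YAML on disk) and executed by run(), which writes
# all artifacts plus a provenance manifest (inputs, config hash, seeds,
# package version) under the run's output directory. A saved config replayed
# with the same seed yields byte-identical artifacts in single-threaded mode.

#' Build a run configuration
#'
#' @param command one of `"synth"`, `"attack"`, `"defend"`, `"detect"`,
#'   `"probe"`, `"report"`, `"viz"`.
#' @param params named list of command-specific parameters (see the
#'   subcommand functions for fields).
#' @param seed integer seed; mandatory for stochastic commands (no silent
#'   default).
#' @param out_dir output directory for artifacts.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(command, params = list(), seed = NULL,
                       out_dir = "run_out", log_level = "info") {
  command <- match.arg(command, c("synth", "attack", "defend", "detect",
                                  "probe", "report", "viz"))
  log_level <- match.arg(log_level, c("quiet", "info", "debug"))
  cfg <- structure(list(command = command, params = params, seed = seed,
                        out_dir = out_dir, log_level = log_level),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @keywords internal
validate_run_config <- function(cfg) {
  stochastic <- c("synth", "attack", "detect")
  if (cfg$command %in% stochastic && is.null(cfg$seed))
    stop(sprintf("config$seed: a seed is mandatory for the stochastic command '%s'",
                 cfg$command))
  p <- cfg$params
  if (cfg$command == "attack") {
    if (!is.null(p$batch) && !is.null(p$n_train) && p$batch > p$n_train)
      stop("config$params$batch: batch must not exceed n_train")
    if (!is.null(p$method) &&
        !p$method %in% c("utap", "psap", "csap", "fgsm"))
      stop("config$params$method: unknown attack method '", p$method, "'")
  }
  if (cfg$command == "defend" && !is.null(p$k) && p$k <= 0)
    stop("config$params$k: kernel size must be positive")
  invisible(cfg)
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(y$command, y$params %||% list(), y$seed, y$out_dir %||% "run_out",
             y$log_level %||% "info")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @keywords internal
run_log <- function(cfg, level, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[cfg$log_level]] >= lv[[level]])
    message(sprintf("[%s] %s", cfg$command, paste0(...)))
}

#' Execute a run configuration
#'
#' Validates the config, executes the requested subcommand via the package's
#' module functions, and writes the artifacts plus a `run_manifest.json`
#' (config hash, seed, package version, artifact list) under `out_dir`.
#'
#' @param cfg a [run_config()].
#' @param dry_run if `TRUE`, validate and print the execution plan without
#'   computing or writing anything.
#' @return invisibly, a list of artifact paths (empty for dry runs).
#' @export
run <- function(cfg, dry_run = FALSE) {
  validate_run_config(cfg)
  if (dry_run) {
    cat(sprintf("plan: command '%s', seed %s, out_dir '%s'\n", cfg$command,
                cfg$seed %||% "none", cfg$out_dir))
    cat("params:", jsonlite::toJSON(cfg$params, auto_unbox = TRUE), "\n")
    return(invisible(list()))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  artifacts <- switch(cfg$command,
    synth = {
      sc <- do.call(synthesis_config,
                    c(p[intersect(names(p), names(formals(synthesis_config)))],
                      list(seed = cfg$seed)))
      ps <- generate_synthetic_patches(sc)
      run_log(cfg, "info", sprintf("generated %d patches", n_patches(ps)))
      list(manifest = write_patchset(ps, cfg$out_dir))
    },
    attack = run_attack_command(cfg),
    defend = {
      ps <- read_patchset(p$manifest)
      flt <- lpf_patchset(ps, lpf_config(p$k))
      run_log(cfg, "info", sprintf("low-pass filtered %d patches (k = %g)",
                                   n_patches(flt), p$k))
      list(manifest = write_patchset(flt, cfg$out_dir))
    },
    probe = {
      enc <- resolve_encoder(p$encoder)
      ps <- read_patchset(p$manifest)
      probe <- train_linear_probe(feature_matrix(enc, ps), ps$labels)
      acc <- evaluate_probe(probe, feature_matrix(enc, ps), ps$labels)
      run_log(cfg, "info", sprintf("training accuracy %.2f%%", acc))
      out <- file.path(cfg$out_dir, "probe.json")
      jsonlite::write_json(list(weights = probe$weights, bias = probe$bias,
                                l2_strength = probe$l2_strength,
                                train_accuracy = acc),
                           out, digits = NA, matrix = "rowmajor")
      list(probe = out)
    },
    detect = {
      clean <- read_patchset(p$clean_manifest)
      atk <- read_patchset(p$attacked_manifest)
      model <- detector_train(clean, atk, p$variant %||% "light",
                              seed = cfg$seed)
      ev <- detector_eval(model, clean, atk)
      run_log(cfg, "info", sprintf("training-set TNR %.2f%% TPR %.2f%%",
                                   ev$tnr, ev$tpr))
      out <- file.path(cfg$out_dir, "detector_eval.json")
      jsonlite::write_json(list(variant = model$variant,
                                parameters = count_params(model),
                                tnr = ev$tnr, tpr = ev$tpr),
                           out, auto_unbox = TRUE, digits = NA)
      list(report = out)
    },
    report = {
      ps <- read_patchset(p$manifest)
      encs <- lapply(p$encoders, resolve_encoder)
      names(encs) <- vapply(encs, function(e) e$name, character(1))
      perts <- lapply(p$perturbations, load_perturbation)
      names(perts) <- names(encs)[seq_along(perts)]
      probes <- lapply(encs, function(e)
        train_linear_probe(feature_matrix(e, ps), ps$labels))
      rep <- transfer_matrix(perts, encs, ps, probes)
      out <- file.path(cfg$out_dir, "transfer_report.json")
      jsonlite::write_json(lapply(unclass(rep), as.data.frame), out,
                           digits = NA)
      list(report = out)
    },
    viz = {
      pt <- load_perturbation(p$perturbation)
      rv <- render_perturbation(pt)
      img_path <- file.path(cfg$out_dir, "perturbation.png")
      png::writePNG(rv$image / 255, img_path)
      hist_path <- file.path(cfg$out_dir, "perturbation_hist.csv")
      utils::write.csv(data.frame(mid = rv$histogram$mids,
                                  count = rv$histogram$counts),
                       hist_path, row.names = FALSE)
      list(image = img_path, histogram = hist_path)
    })
  cfg_path <- file.path(cfg$out_dir, "run_config.yaml")
  write_run_config(cfg, cfg_path)
  manifest <- list(command = cfg$command, seed = cfg$seed,
                   config_hash = config_hash(unclass(cfg)),
                   package_version = as.character(utils::packageVersion("utapr")),
                   artifacts = lapply(artifacts, as.character))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}

# Encoder registry: "tiny-vit[-seed[-size[-width]]]" builds the bundled ViT;
# anything else must be an RDS file holding an object satisfying the encoder
# contract (the adapter entry point for user-supplied models).
#' @keywords internal
resolve_encoder <- function(spec) {
  if (inherits(spec, "encoder")) return(spec)
  if (grepl("^tiny-vit", spec)) {
    parts <- strsplit(spec, "-")[[1L]]
    seed <- if (length(parts) >= 3L) as.integer(parts[3L]) else 0L
    size <- if (length(parts) >= 4L) as.integer(parts[4L]) else 224L
    width <- if (length(parts) >= 5L) as.integer(parts[5L]) else 192L
    return(build_tiny_vit(seed = seed, input_size = size, width = width))
  }
  if (file.exists(spec)) {
    enc <- readRDS(spec)
    if (!inherits(enc, "encoder")) stop("file does not hold an encoder: ", spec)
    return(enc)
  }
  stop("unknown encoder spec: ", spec)
}

#' @keywords internal
run_attack_command <- function(cfg) {
  p <- cfg$params
  ps <- read_patchset(p$manifest)
  enc_specs <- p$encoder
  encs <- lapply(enc_specs, resolve_encoder)
  names(encs) <- vapply(encs, function(e) e$name, character(1))
  method <- p$method %||% "utap"
  out_tiff <- file.path(cfg$out_dir, paste0(method, "_perturbation.tiff"))
  if (method == "utap") {
    ac <- attack_config(epsilon_8bit = p$epsilon %||% 20,
                        theta = p$theta %||% 10,
                        epochs = p$epochs %||% 10L,
                        batch = p$batch %||% 5L,
                        n_train = p$n_train %||% n_patches(ps),
                        n_mask = p$n_mask %||% 130L,
                        seed = cfg$seed,
                        objective = p$objective %||% "cosine",
                        lpf_in_loop = if (!is.null(p$lpf_k))
                          lpf_config(p$lpf_k) else NULL,
                        switch_interval = p$switch_interval %||% 8L)
    res <- utap_train(ps, encs, ac)
    save_perturbation(res$perturbation, out_tiff)
    trace_csv <- file.path(cfg$out_dir, "loss_trace.csv")
    utils::write.csv(res$trace, trace_csv, row.names = FALSE)
    run_log(cfg, "info",
            sprintf("final objective %.4f, max|p| = %.5f",
                    utils::tail(res$trace$objective, 1L),
                    max(abs(res$perturbation$values))))
    list(perturbation = out_tiff, trace = trace_csv)
  } else {
    enc <- encs[[1L]]
    probe <- train_linear_probe(feature_matrix(enc, ps), ps$labels)
    if (method == "psap") {
      pt <- psap_train(ps$images[[1L]], ps$labels[1L], enc, probe,
                       bound = p$epsilon %||% 20)
      save_perturbation(pt, out_tiff)
      list(perturbation = out_tiff)
    } else if (method == "csap") {
      cls <- p$class %||% ps$labels[1L]
      sel <- ps[ps$labels == cls]
      pt <- csap_train(sel, cls, enc, probe, bound = p$epsilon %||% 20,
                       seed = cfg$seed)
      save_perturbation(pt, out_tiff)
      list(perturbation = out_tiff)
    } else {
      atk <- ps
      for (i in seq_len(n_patches(ps)))
        atk$images[[i]] <- fgsm(ps$images[[i]], ps$labels[i], enc, probe,
                                (p$epsilon %||% 20) / 255)
      list(manifest = write_patchset(atk, cfg$out_dir))
    }
  }
}
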