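# ---------------------------------------------------------------------------
# Run configuration, full-pipeline orchestration, feature/result persistence
# and the run manifest.
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed for the run.
#' @param duration Simulated session duration in seconds.
#' @param cadence Simulated cadence (steps/s).
#' @param m Simulated modulation depth (scalar, applied to every
#'   channel/band).
#' @param decoders Decoder labels to evaluate.
#' @param subsets Channel subsets to evaluate.
#' @param cnn List of [cnn_config()] overrides.
#' @param analyses Which analyses to run (`"tfmap"`, `"mi"`).
#' @param session Path to an existing session file (skips simulation).
#' @param bands Optional band table overriding [band_specs()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "lfpdecode-run", seed = 0, duration = 60,
                       cadence = 0.72, m = 0.7,
                       decoders = c("pls", "lasso"), subsets = "all",
                       cnn = list(), analyses = c("tfmap", "mi"),
                       session = NULL, bands = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 duration = duration, cadence = cadence, m = m,
                 decoders = decoders, subsets = subsets, cnn = cnn,
                 analyses = analyses, session = session, bands = bands),
            class = "run_config")
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  base <- run_config()
  known <- names(base)
  extra <- setdiff(names(config), known)
  if (length(extra) > 0)
    stop(sprintf("unknown run-config field(s): %s", paste(extra, collapse = ", ")))
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  bad <- !vapply(base$decoders, function(d)
    d %in% c("cnn", "pls", "lasso"), logical(1))
  if (any(bad)) stop("decoders must be among cnn, pls, lasso")
  bad <- !vapply(base$subsets, function(s)
    s %in% c("all", "lateral", "dorsal", "left", "right"), logical(1))
  if (any(bad)) stop("unknown channel subset in run config")
  base
}

stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline
#'
#' Simulate (unless a session file is supplied), preprocess, decode every
#' requested decoder x channel subset, run the analyses, and write all
#' tables plus a JSON manifest (seeds, package version, config hash and a
#' checksum per output file).
#'
#' @param config A [run_config()], a list of overrides, or a path to a JSON
#'   config file.
#' @param verbose Log stage timings (default TRUE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  session <- stage("simulate", verbose, {
    if (!is.null(config$session)) {
      read_session(config$session)
    } else {
      cfg <- synth_config(duration = config$duration, seed = config$seed,
                          gait = gait_model(cadence = config$cadence),
                          coupling = coupling_spec(m = matrix(config$m, 8, 6)))
      s <- generate_session(cfg)
      p <- file.path(config$out_dir, "session.json")
      write_session(s, p)
      outputs <- c(outputs, p)
      s
    }
  })

  prep <- stage("preprocess", verbose, {
    bands <- if (is.null(config$bands)) band_specs() else
      as.data.frame(config$bands, stringsAsFactors = FALSE)
    preprocess_session(session, bands = bands)
  })

  results <- stage("decode", verbose, {
    rows <- list()
    for (dec in config$decoders) for (sub in config$subsets) {
      ccfg <- do.call(cnn_config, c(list(seed = config$seed), config$cnn))
      rows[[length(rows) + 1]] <-
        crossvalidate(prep, decoder = dec, subset = sub, config = ccfg)
    }
    do.call(rbind, rows)
  })
  res_path <- file.path(config$out_dir, "decode_results.csv")
  utils::write.csv(results, res_path, row.names = FALSE)
  outputs <- c(outputs, res_path)

  stage("analyze", verbose, {
    if ("tfmap" %in% config$analyses) {
      cyc <- segment_gait_cycles(session)
      tf <- cycle_average(prep$features$env, prep$features$t, cyc)
      for (what in c("mean", "pct_change")) {
        m <- tf[[what]]
        flat <- do.call(rbind, lapply(seq_len(dim(m)[1]), function(c_i) {
          d <- as.data.frame(m[c_i, , ])
          names(d) <- paste0("bin", seq_len(ncol(d)))
          cbind(data.frame(channel = c_i, band = band_specs()$name), d)
        }))
        p <- file.path(config$out_dir, paste0("tfmap_", what, ".csv"))
        utils::write.csv(flat, p, row.names = FALSE)
        outputs <- c(outputs, p)
      }
    }
    if ("mi" %in% config$analyses) {
      mm <- mi_matrix(prep$features, session$kinematics, session$kin_fs)
      flat <- do.call(rbind, lapply(seq_len(dim(mm)[1]), function(c_i) {
        d <- as.data.frame(mm[c_i, , ])
        cbind(data.frame(channel = c_i, feature = dimnames(mm)[[2]]), d)
      }))
      p <- file.path(config$out_dir, "mi_matrix.csv")
      utils::write.csv(flat, p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
    NULL
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  cfg_file <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  outputs <- c(outputs, cfg_file)
  manifest <- list(
    package = "lfpdecode",
    version = as.character(utils::packageVersion("lfpdecode")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  man_path <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE), man_path)
  invisible(manifest)
}
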