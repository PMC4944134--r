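#' @title Run configuration and result persistence
#' @name run-config
#' @keywords internal
NULL

# fixed default seed so that default runs are exactly reproducible
.default_seed <- 20160714L

config_defaults <- function() {
  list(J = 400L,
       mc = list(dt = 1e-3, n_paths = 1e4, t_max = NULL,
                 seed = .default_seed),
       output_dir = ".")
}

#' Load and validate a run configuration
#'
#' Reads a structured configuration (JSON or YAML, auto-detected from the
#' file extension) describing a full run: model parameters, noise
#' specification (either `sigma`/`epsilon`/`alpha` or `lambda`/`alpha`
#' under the constrained budget `sigma + epsilon = 1`), domain / target /
#' window interval lists, solver resolution `J`, and Monte Carlo settings.
#' Every component invariant is validated on load; unknown keys are
#' rejected; omitted optional fields are filled with the documented
#' defaults (J = 400, dt = 1e-3, n_paths = 1e4, seed = 20160714).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An object of class `run_config`: a named list with `model`
#'   ([tfa_params()]), `noise` ([noise_spec()]), optional `domain`,
#'   `target`, `window`, `J`, `mc`, `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format '.", ext,
                     "': use .json or .yaml"))
  known <- c("model", "noise", "domain", "target", "window", "J", "mc",
             "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(raw$model)) stop("config must contain a 'model' block")
  mk <- setdiff(names(raw$model), c("k_f", "K_d", "k_d", "R_bas"))
  if (length(mk)) stop("unknown model keys: ", paste(mk, collapse = ", "))
  model <- with(raw$model, tfa_params(k_f, K_d, k_d, R_bas))

  if (is.null(raw$noise)) stop("config must contain a 'noise' block")
  nz <- raw$noise
  nk <- setdiff(names(nz), c("sigma", "epsilon", "alpha", "lambda",
                             "constrained"))
  if (length(nk)) stop("unknown noise keys: ", paste(nk, collapse = ", "))
  if (is.null(nz$alpha)) stop("noise block must give 'alpha'")
  noise <- if (!is.null(nz$lambda)) {
    if (!is.null(nz$sigma) || !is.null(nz$epsilon)) {
      stop("give either 'lambda' or 'sigma'/'epsilon', not both")
    }
    rcf_setting(nz$lambda, nz$alpha)
  } else {
    noise_spec(nz$sigma, nz$epsilon, nz$alpha,
               constrained = isTRUE(nz$constrained))
  }

  defs <- config_defaults()
  mc <- utils::modifyList(defs$mc, as.list(raw$mc %||% list()))
  mk2 <- setdiff(names(mc), c("dt", "n_paths", "t_max", "seed"))
  if (length(mk2)) stop("unknown mc keys: ", paste(mk2, collapse = ", "))
  if (mc$dt <= 0) stop("mc field 'dt' must be positive")
  if (mc$n_paths < 1) stop("mc field 'n_paths' must be >= 1")

  as_ints <- function(x) if (is.null(x)) NULL else {
    m <- if (is.list(x)) do.call(rbind, x) else matrix(unlist(x), ncol = 2,
                                                       byrow = TRUE)
    m
  }
  cfg <- list(model = model, noise = noise,
              domain = if (!is.null(raw$domain))
                as_domain1d(as_ints(raw$domain)),
              target = if (!is.null(raw$target)) as_target(as_ints(raw$target)),
              window = if (!is.null(raw$window))
                as_domain1d(as_ints(raw$window)),
              J = as.integer(raw$J %||% defs$J),
              mc = mc,
              output_dir = raw$output_dir %||% defs$output_dir)
  if (!is.null(cfg$target) && !is.null(cfg$domain)) {
    check_target_exterior(cfg$target, cfg$domain)
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration
#'
#' Serialises a [load_config()] object back to JSON or YAML so that
#' `load_config(write_config(cfg, path))` round-trips.
#'
#' @param cfg a `run_config` object.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  ints <- function(m) if (is.null(m)) NULL else
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  raw <- list(model = cfg$model[c("k_f", "K_d", "k_d", "R_bas")],
              noise = list(sigma = cfg$noise$sigma,
                           epsilon = cfg$noise$epsilon,
                           alpha = cfg$noise$alpha),
              domain = ints(cfg$domain), target = ints(cfg$target),
              window = ints(cfg$window), J = cfg$J, mc = cfg$mc,
              output_dir = cfg$output_dir)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(raw, path, auto_unbox = TRUE,
                                     digits = NA, null = "null"),
         yaml = ,
         yml = yaml::write_yaml(raw, path),
         stop("unsupported config format '.", ext, "'"))
  invisible(path)
}

#' Write a result table to annotated CSV
#'
#' Writes a [sweep_mfet()] / [sweep_fep()] table or a [solve_mfet()] /
#' [solve_fep()] field to CSV, preceded by a commented header block of
#' `# key=value` lines recording the generating parameters. Numbers are
#' written with 6 significant digits. Read back with [read_table_csv()].
#'
#' @param table a `sweep_table` data.frame or a `field_solution`.
#' @param path output file path.
#' @param meta optional named list of extra `key=value` header entries.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path, meta = list()) {
  if (inherits(table, "field_solution")) {
    hdr <- c(kind = table$kind, J = table$J,
             sigma = table$noise$sigma, epsilon = table$noise$epsilon,
             alpha = table$noise$alpha,
             domain = paste(sprintf("%g:%g", table$domain[, 1],
                                    table$domain[, 2]), collapse = ";"))
    df <- data.frame(x = table$x, value = table$values)
  } else if (inherits(table, "sweep_table") || is.data.frame(table)) {
    hdr <- c(kind = "sweep")
    df <- as.data.frame(table)
  } else stop("cannot write object of class ", class(table)[1])
  hdr <- c(hdr, unlist(meta))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(hdr), as.character(hdr)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotated CSV written by [write_table_csv()]
#'
#' @param path file path.
#' @return A data.frame; the parsed `# key=value` header is attached as
#'   attribute `"meta"`.
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# ", "", hdr)
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  attr(df, "meta") <- as.list(meta)
  df
}
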