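# Configuration parsing, fixture generation and the command-line
# interface.  All unit conversion happens here; the computational layers
# work in CGS + hours.

.config_keys <- c("material", "rho", "k", "d0", "c0", "t",
                  "eta1", "eta2", "cutoff_low", "cutoff_high",
                  "ratio_lo", "ratio_hi", "dose_lo", "dose_hi", "grid_n",
                  "ec50_ion", "ec50_nf", "out", "format")

#' Parse a run configuration
#'
#' Reads a flat key-value (YAML) file or list describing one run.
#' Quantities with units (`k`, `d0`, `t`) accept either bare numbers in
#' the reporting units (ng/cm^2/h, nm, h) or strings such as
#' `"37.95 ng/cm2/h"`.  `material` (`silver`/`copper`) resolves the
#' density unless `rho` is given explicitly.  Unknown keys are rejected
#' by name; cutoffs default to 0.10/0.90 and the region bounds to the
#' standard assumption region.
#'
#' @param source path to a YAML file, or a named list.
#' @return object of class `run_config`: a named list with all values in
#'   internal units (`k` g/cm^2/h, `d0` cm, `t` h) plus resolved
#'   defaults.
#' @export
parse_config <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  if (!is.list(cfg)) stop("config source must be a file path or a list")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  out <- list()
  if (!is.null(cfg$material)) {
    preset <- material_preset(match.arg(cfg$material, c("silver", "copper")))
    out$material <- preset$name
    out$rho <- preset$rho
  }
  if (!is.null(cfg$rho)) out$rho <- parse_quantity(cfg$rho, "density")
  if (is.null(out$rho)) stop("missing mandatory field: material or rho")
  if (!is.null(cfg$k)) out$k <- parse_quantity(cfg$k, "k")
  if (!is.null(cfg$d0)) out$d0 <- parse_quantity(cfg$d0, "length")
  if (!is.null(cfg$c0)) out$c0 <- parse_quantity(cfg$c0, "conc")
  if (!is.null(cfg$t)) out$t <- parse_quantity(cfg$t, "time")
  for (key in c("eta1", "eta2", "ec50_ion", "ec50_nf"))
    if (!is.null(cfg[[key]])) {
      v <- cfg[[key]]
      if (!is.numeric(v)) stop("non-numeric value for config key '", key, "'")
      out[[key]] <- v
    }
  out$eta1 <- out$eta1 %||% 1
  out$eta2 <- out$eta2 %||% 1
  out$cutoffs <- c(cfg$cutoff_low %||% 0.10, cfg$cutoff_high %||% 0.90)
  if (!is.numeric(out$cutoffs) || out$cutoffs[1L] >= out$cutoffs[2L])
    stop("cutoffs must be numeric with cutoff_low < cutoff_high")
  out$region <- region_spec(
    ratio_lo = cfg$ratio_lo %||% 1, ratio_hi = cfg$ratio_hi %||% 5,
    dose_lo = cfg$dose_lo %||% 0.1, dose_hi = cfg$dose_hi %||% 5,
    grid_n = cfg$grid_n %||% 201L)
  out$out <- cfg$out
  out$format <- cfg$format %||% "csv"
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration back to YAML
#'
#' Inverse of [parse_config()]: values are emitted in the reporting
#' units so that `parse_config(write_config(cfg, f))` round-trips.
#'
#' @param cfg a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "run_config")) stop("'cfg' must be a run_config")
  flat <- list()
  if (!is.null(cfg$material)) flat$material <- cfg$material else
    flat$rho <- cfg$rho
  if (!is.null(cfg$k)) flat$k <- paste(format(k_g_to_ng(cfg$k), digits = 15),
                                       "ng/cm2/h")
  if (!is.null(cfg$d0)) flat$d0 <- paste(format(d_cm_to_nm(cfg$d0),
                                                digits = 15), "nm")
  if (!is.null(cfg$c0)) flat$c0 <- cfg$c0
  if (!is.null(cfg$t)) flat$t <- paste(format(cfg$t, digits = 15), "h")
  flat$eta1 <- cfg$eta1
  flat$eta2 <- cfg$eta2
  flat$cutoff_low <- cfg$cutoffs[1L]
  flat$cutoff_high <- cfg$cutoffs[2L]
  flat$ratio_lo <- cfg$region$ratio_lo
  flat$ratio_hi <- cfg$region$ratio_hi
  flat$dose_lo <- cfg$region$dose_lo
  flat$dose_hi <- cfg$region$dose_hi
  flat$grid_n <- cfg$region$grid_n
  if (!is.null(cfg$ec50_ion)) flat$ec50_ion <- cfg$ec50_ion
  if (!is.null(cfg$ec50_nf)) flat$ec50_nf <- cfg$ec50_nf
  if (!is.null(cfg$out)) flat$out <- cfg$out
  flat$format <- cfg$format
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Generate synthetic nanoform specifications for testing
#'
#' Draws reproducible random nanoform batches spanning the realistic
#' screening range: log-uniform k in \[1e-4, 1e3\] ng/cm^2/h, diameters
#' log-uniform in \[5, 200\] nm, material drawn from the silver/copper
#' presets, and total concentrations log-uniform in \[1e-4, 1e-1\] g/L
#' (typical aquatic test doses).
#'
#' @param n number of specs.
#' @param seed RNG seed.
#' @return data frame with columns `name`, `material`,
#'   `k_ng_cm2_h`, `rho_g_cm3`, `d0_nm`, `c0_g_per_L`.
#' @export
generate_fixture_specs <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  mat <- sample(c("silver", "copper"), n, replace = TRUE)
  data.frame(
    name = sprintf("nf%03d", seq_len(n)),
    material = mat,
    k_ng_cm2_h = 10^stats::runif(n, -4, 3),
    rho_g_cm3 = vapply(mat, function(m) material_preset(m)$rho, numeric(1),
                       USE.NAMES = FALSE),
    d0_nm = 10^stats::runif(n, log10(5), log10(200)),
    c0_g_per_L = 10^stats::runif(n, -4, -1)
  )
}

# ---- command-line interface -------------------------------------------

.cli_usage <- paste(
  "usage: nanotoxkin <subcommand> [--flag value ...]",
  "",
  "subcommands:",
  "  classify    classify a nanoform (needs k, d0, t, material|rho[, c0, ec50s])",
  "  critical-k  critical rate constant for a Pt boundary (pt, d0, t, material|rho)",
  "  critical-t  critical exposure time (pt, k, d0, material|rho)",
  "  thresholds  compute Pt regime boundaries for a region (eta1, eta2[, region])",
  "  table       write the silver/copper-style critical-k table (material)",
  "  contr       ion-contribution time course (k, d0, c0, t, ec50s, material|rho)",
  "  scan        (A, B) grid of ion contribution at one tau (tau, eta1, eta2)",
  "  fixtures    synthetic nanoform spec sets (n, seed)",
  "",
  "common flags: --config FILE, --out FILE, --scenario '1,1'|'1,5'|'4,8',",
  "  --material silver|copper, --k '37.95 ng/cm2/h', --d0 '10 nm', --t '72 h'",
  sep = "\n")

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "' (flags are --name value)")
    key <- sub("^--", "", a)
    if (grepl("=", key)) {
      flags[[sub("=.*", "", key)]] <- sub("^[^=]*=", "", key)
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " is missing a value")
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

.flag_num <- function(flags, name, kind = NULL, default = NULL) {
  v <- flags[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required flag --", name)
    return(default)
  }
  if (is.null(kind)) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("flag --", name, " must be numeric, got '", v, "'")
    return(x)
  }
  num <- suppressWarnings(as.numeric(v))
  parse_quantity(if (!is.na(num)) num else v, kind)
}

.cli_resolve_rho <- function(flags) {
  if (!is.null(flags$material)) material_preset(flags$material)$rho
  else if (!is.null(flags$rho)) .flag_num(flags, "rho")
  else stop("supply --material or --rho")
}

.cli_thresholds <- function(flags) {
  if (!is.null(flags$scenario)) {
    etas <- as.numeric(strsplit(flags$scenario, ",")[[1L]])
    if (length(etas) != 2L || any(is.na(etas)))
      stop("--scenario must look like '1,1', '1,5' or '4,8'")
    reference_thresholds(etas[1L], etas[2L])
  } else {
    reference_thresholds(1, 1)
  }
}

.cli_emit <- function(df, flags) {
  if (!is.null(flags$out)) {
    utils::write.csv(df, flags$out, row.names = FALSE)
    message("wrote ", nrow(df), " rows to ", flags$out)
  } else {
    utils::write.csv(df, stdout(), row.names = FALSE)
  }
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/nanotoxkin` script.  See the
#' package README for the subcommands.  Usage errors print a diagnostic
#' and return exit status 2; success returns 0.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly.
#' @export
nanotox_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L || args[[1L]] %in% c("-h", "--help", "help")) {
      cat(.cli_usage, "\n")
      return(invisible(0L))
    }
    cmd <- args[[1L]]
    flags <- .parse_flags(args[-1L])
    if (!is.null(flags$config)) {
      cfg <- parse_config(flags$config)
      defaults <- list(
        rho = cfg$rho, material = cfg$material,
        k = if (!is.null(cfg$k)) k_g_to_ng(cfg$k),
        d0 = if (!is.null(cfg$d0)) d_cm_to_nm(cfg$d0),
        c0 = cfg$c0, t = cfg$t, eta1 = cfg$eta1, eta2 = cfg$eta2,
        ec50_ion = cfg$ec50_ion, ec50_nf = cfg$ec50_nf, out = cfg$out)
      for (key in names(defaults))
        if (is.null(flags[[key]]) && !is.null(defaults[[key]]))
          flags[[key]] <- defaults[[key]]
    }
    message("nanotoxkin ", cmd, ": ",
            paste(names(flags), unlist(lapply(flags, format)),
                  sep = "=", collapse = " "))
    switch(cmd,
      "critical-k" = {
        k <- critical_k(.flag_num(flags, "pt"), .cli_resolve_rho(flags),
                        d_cm_to_nm(.flag_num(flags, "d0", "length")),
                        .flag_num(flags, "t", "time"))
        cat(format(.round_k_table(k)), "\n")
      },
      "critical-t" = {
        spec <- nanoform(k = k_g_to_ng(.flag_num(flags, "k", "k")),
                         rho = .cli_resolve_rho(flags),
                         d0 = d_cm_to_nm(.flag_num(flags, "d0", "length")),
                         c0 = 1)
        cat(format(round(critical_t(.flag_num(flags, "pt"), spec), 2)), "\n")
      },
      "classify" = {
        spec <- nanoform(k = k_g_to_ng(.flag_num(flags, "k", "k")),
                         rho = .cli_resolve_rho(flags),
                         d0 = d_cm_to_nm(.flag_num(flags, "d0", "length")),
                         c0 = .flag_num(flags, "c0", "conc", default = 1e-3))
        res <- classify_nanoform(
          spec, .flag_num(flags, "t", "time"), .cli_thresholds(flags),
          ec50_ion = if (!is.null(flags$ec50_ion))
            .flag_num(flags, "ec50_ion", "conc"),
          ec50_nf = if (!is.null(flags$ec50_nf))
            .flag_num(flags, "ec50_nf", "conc"))
        print(res)
      },
      "thresholds" = {
        region <- region_spec(
          ratio_lo = .flag_num(flags, "ratio_lo", default = 1),
          ratio_hi = .flag_num(flags, "ratio_hi", default = 5),
          dose_lo = .flag_num(flags, "dose_lo", default = 0.1),
          dose_hi = .flag_num(flags, "dose_hi", default = 5),
          grid_n = .flag_num(flags, "grid_n", default = 201))
        print(find_pt_boundaries(region,
                                 eta1 = .flag_num(flags, "eta1", default = 1),
                                 eta2 = .flag_num(flags, "eta2", default = 1)))
      },
      "table" = {
        mat <- material_preset(flags$material %||% "silver")
        .cli_emit(generate_table(mat), flags)
      },
      "contr" = {
        spec <- nanoform(k = k_g_to_ng(.flag_num(flags, "k", "k")),
                         rho = .cli_resolve_rho(flags),
                         d0 = d_cm_to_nm(.flag_num(flags, "d0", "length")),
                         c0 = .flag_num(flags, "c0", "conc"))
        t_max <- .flag_num(flags, "t", "time")
        n <- .flag_num(flags, "n", default = 101)
        tc <- suspension_effect_timecourse(
          spec,
          ion_curve = hill_curve(.flag_num(flags, "ec50_ion", "conc"),
                                 .flag_num(flags, "eta1", default = 1)),
          nf_curve = hill_curve(.flag_num(flags, "ec50_nf", "conc"),
                                .flag_num(flags, "eta2", default = 1)),
          times = seq(0, t_max, length.out = n))
        .cli_emit(tc, flags)
      },
      "scan" = {
        region <- region_spec(grid_n = .flag_num(flags, "grid_n",
                                                 default = 101))
        .cli_emit(region_scan(region, .flag_num(flags, "tau"),
                              eta1 = .flag_num(flags, "eta1", default = 1),
                              eta2 = .flag_num(flags, "eta2", default = 1)),
                  flags)
      },
      "fixtures" = {
        .cli_emit(generate_fixture_specs(
          n = .flag_num(flags, "n", default = 20),
          seed = .flag_num(flags, "seed", default = 1)), flags)
      },
      stop("unknown subcommand '", cmd, "'")
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(.cli_usage)
    2L
  })
  invisible(status)
}
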