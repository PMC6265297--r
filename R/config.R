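#' Load and validate a run configuration
#'
#' Reads a YAML run configuration describing the constructs to simulate
#' (each a two-state Boltzmann truth standing for one suppression
#' construct), the recording protocol, the cell model, analysis options
#' and the amide/ester pairs to difference into gating free energies.
#' Unknown keys are rejected by name; missing sections receive the
#' package defaults.  `save_config(load_config(path))` round-trips.
#'
#' @param path path to a YAML configuration.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_defaults <- function() {
  list(
    seed = 1L,
    out_prefix = "vsgating_run",
    temperature_K = 295.15,
    protocol = list(V_hold = -80, step_from = -80, step_to = 60,
                    step_by = 5, step_duration = 30, V_tail = -80,
                    tail_duration = 30, pre_duration = 5, sample_rate = 10),
    cell = list(C_lin = 200, tau_clamp = 0.3, g_leak = 1, E_leak = 0,
                noise_sd = 0.03),
    analysis = list(window = c(2, 4), vrev = 0, n_sub = 8, blank = 0.3,
                    cap_range = c(50, 70)),
    constructs = list(),
    pairs = list()
  )
}

validate_config <- function(raw) {
  def <- config_defaults()
  bad <- setdiff(names(raw), c(names(def), "charge"))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- def
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  for (sec in c("protocol", "cell", "analysis")) {
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop("unknown config key(s) in ", sec, ": ", paste(bad, collapse = ", "))
    cfg[[sec]] <- utils::modifyList(def[[sec]], cfg[[sec]])
  }
  if (cfg$cell$noise_sd < 0) stop("invalid value for key noise_sd: must be >= 0")
  if (cfg$protocol$sample_rate <= 0) stop("invalid value for key sample_rate")
  for (co in cfg$constructs) {
    need <- setdiff(c("name", "scheme"), names(co))
    if (length(need)) stop("construct missing key(s): ", paste(need, collapse = ", "))
    sch <- co$scheme
    if (!is.null(sch$z) && sch$z <= 0)
      stop("invalid value for key z in construct ", co$name)
    if (!is.null(sch$k0) && sch$k0 <= 0)
      stop("invalid value for key k0 in construct ", co$name)
  }
  structure(cfg, class = "run_config")
}

config_checksum <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

provenance_header <- function(config) {
  c(sprintf("# vsgating %s", as.character(utils::packageVersion("vsgating"))),
    sprintf("# config_checksum: %s", config_checksum(config)),
    sprintf("# seed: %d", as.integer(config$seed)))
}

write_csv_with_provenance <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written with a provenance header
#' @param path file path.
#' @return data.frame.
#' @export
read_csv_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

construct_scheme <- function(co, temperature_K) {
  sch <- co$scheme
  type <- if (!is.null(sch$type)) sch$type else "two_state"
  if (type == "two_state") {
    build_two_state_scheme(
      z = sch$z, Vd = sch$Vd,
      k0 = if (!is.null(sch$k0)) sch$k0 else 0.12,
      delta = if (!is.null(sch$delta)) sch$delta else 0.8,
      N = if (!is.null(sch$N)) sch$N else 2.5e6,
      gamma = if (!is.null(sch$gamma)) sch$gamma else 2e-11,
      Vrev = if (!is.null(sch$Vrev)) sch$Vrev else 0,
      conducting = if (!is.null(sch$conducting)) sch$conducting else TRUE,
      temperature_K = temperature_K)
  } else if (type == "sequential") {
    build_sequential_scheme(sch$transitions,
                            N = if (!is.null(sch$N)) sch$N else 1e10,
                            conducting = isTRUE(sch$conducting),
                            temperature_K = temperature_K)
  } else stop("unknown scheme type: ", type)
}

#' Run the complete simulation-plus-analysis pipeline from a config
#'
#' For each configured construct: simulate test and P/N companion
#' sweeps, subtract, build the G-V by the construct's method (tail or
#' chord) and fit a Boltzmann.  For each configured amide/ester pair:
#' compute the gating free-energy perturbation.  If a `charge` section
#' is present, run the gating-charge pipeline as well.  All outputs are
#' CSV files with provenance headers plus a machine-readable JSON
#' summary; everything is deterministic for a fixed config seed.
#'
#' @param config a `run_config` from [load_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the summary list (per-construct fits, ddG table,
#'   charge fit, file paths, `any_flagged`).
#' @export
run_end_to_end <- function(config, out_dir = dirname(config$out_prefix)) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) && nzchar(out_dir) && out_dir != ".")
    dir.create(out_dir, recursive = TRUE)
  pr <- config$protocol
  protocol <- voltage_protocol(
    V_hold = pr$V_hold,
    step_voltages = seq(pr$step_from, pr$step_to, by = pr$step_by),
    step_duration = pr$step_duration, V_tail = pr$V_tail,
    tail_duration = pr$tail_duration, pre_duration = pr$pre_duration,
    sample_rate = pr$sample_rate)
  fits <- list()
  rows <- list()
  for (k in seq_along(config$constructs)) {
    co <- config$constructs[[k]]
    scheme <- construct_scheme(co, config$temperature_K)
    cell <- cell_model(C_lin = config$cell$C_lin,
                       tau_clamp = config$cell$tau_clamp,
                       g_leak = config$cell$g_leak,
                       E_leak = config$cell$E_leak,
                       noise_sd = config$cell$noise_sd,
                       seed = config$seed + 7L * k)
    test <- simulate_sweeps(scheme, protocol, cell)
    sub_cell <- cell; sub_cell$seed <- cell$seed + 1000003L
    sub <- simulate_sweeps(scheme,
                           p_over_n_subpulses(protocol, config$analysis$n_sub,
                                              V_sub_hold = -110),
                           sub_cell)
    corrected <- p_over_n_subtract(test, sub)
    method <- if (!is.null(co$gv_method)) co$gv_method else "tail"
    gv <- if (method == "chord")
      gv_from_chord(corrected, Vrev = config$analysis$vrev)
    else gv_from_tails(corrected, window = config$analysis$window)
    fit <- fit_boltzmann(gv, temperature_K = config$temperature_K)
    fits[[co$name]] <- fit
    rows[[k]] <- data.frame(construct = co$name, method = method,
                            Gmax = fit$Gmax, Vd = fit$Vd, z = fit$z,
                            residual = fit$residual,
                            converged = fit$converged)
  }
  gv_df <- do.call(rbind, rows)
  ddg_rows <- lapply(config$pairs, function(p) {
    dd <- delta_delta_g(fits[[p$aa]], fits[[p$ah]],
                        label_aa = p$aa, label_ah = p$ah)
    data.frame(site = p$site, aa = p$aa, ah = p$ah,
               ddG_kcal_mol = dd$value, term_aa = dd$term_aa,
               term_ah = dd$term_ah)
  })
  ddg_df <- if (length(ddg_rows)) do.call(rbind, ddg_rows) else NULL
  charge_fit <- NULL
  if (!is.null(config$charge)) {
    run <- charge_recovery_run(
      scheme = construct_scheme(list(scheme = config$charge),
                                config$temperature_K),
      cell = study_cell(noise_sd = config$cell$noise_sd,
                        seed = config$seed + 101L,
                        C_lin = config$cell$C_lin,
                        g_leak = config$cell$g_leak))
    charge_fit <- run$fit
    write_csv_with_provenance(run$qv, paste0(config$out_prefix, "_qv.csv"),
                              config)
  }
  files <- paste0(config$out_prefix, c("_gv_fits.csv", "_ddg.csv"))
  write_csv_with_provenance(gv_df, files[1], config)
  if (!is.null(ddg_df)) write_csv_with_provenance(ddg_df, files[2], config)
  any_flagged <- any(!gv_df$converged) ||
    (!is.null(charge_fit) && !isTRUE(charge_fit$converged))
  summary <- list(gv_fits = gv_df, ddg = ddg_df, charge_fit = charge_fit,
                  files = files, seed = config$seed,
                  any_flagged = any_flagged)
  jsonlite::write_json(
    list(seed = config$seed, checksum = config_checksum(config),
         gv_fits = gv_df, ddg = ddg_df,
         charge_fit = if (!is.null(charge_fit)) unclass(charge_fit),
         any_flagged = any_flagged),
    paste0(config$out_prefix, "_summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

#' Gating free-energy table from printed Boltzmann parameters
#'
#' Computes per-site ddG = (z F Vd)_aa - (z F Vd)_ah directly from a
#' table of fitted parameters (columns construct, site, kind, Vd, z and
#' optionally Vd_sd, z_sd), pairing each site's amide control with its
#' ester variant.  Uncertainty, when the sd columns are present, is the
#' first-order (delta-method) propagation
#' `sd(zFVd) = F sqrt(Vd^2 sd_z^2 + z^2 sd_Vd^2)` per construct,
#' combined in quadrature — a convention choice, since error bars on a
#' product can be propagated in more than one way.
#'
#' @param params data.frame like [gating_parameter_table()].
#' @return data.frame (site, ddG_kcal_mol, ddG_sd, term_aa, term_ah).
#' @export
ddg_from_parameters <- function(params = gating_parameter_table()) {
  Fk <- phys_constants()$F_kcal
  term <- function(r) r$z * Fk * r$Vd / 1000
  term_sd <- function(r) {
    if (is.null(r$z_sd) || is.null(r$Vd_sd)) return(NA_real_)
    Fk * sqrt((r$Vd / 1000)^2 * r$z_sd^2 + r$z^2 * (r$Vd_sd / 1000)^2)
  }
  sites <- unique(params$site[params$kind == "ah"])
  rows <- lapply(sites, function(s) {
    aa <- params[params$site == s & params$kind == "aa", ][1, ]
    ah <- params[params$site == s & params$kind == "ah", ][1, ]
    data.frame(site = s, ddG_kcal_mol = term(aa) - term(ah),
               ddG_sd = sqrt(term_sd(aa)^2 + term_sd(ah)^2),
               term_aa = term(aa), term_ah = term(ah),
               dVd = ah$Vd - aa$Vd)
  })
  do.call(rbind, rows)
}
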