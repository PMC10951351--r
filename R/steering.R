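# Plain-text steering files ---------------------------------------------
#
# Dialect: INI-style sections of `key = value` lines. `#` starts a comment.
# Sections: [study], [groups], [bma], and one [scenario NAME] per error
# scenario. Error magnitudes accept percentages ("50%") or proportions
# ("0.5"), mirroring how the study tables quote error magnitudes.

parse_value_num <- function(value, line) {
  v <- trimws(strsplit(value, ",")[[1]])
  pct <- grepl("%$", v)
  num <- suppressWarnings(as.numeric(sub("%$", "", v)))
  if (anyNA(num)) stop(sprintf("line %d: cannot parse numeric value '%s'",
                               line, value), call. = FALSE)
  num[pct] <- num[pct] / 100
  num
}

parse_value_chr <- function(value) trimws(strsplit(value, ",")[[1]])

steering_keys <- list(
  study = c("n_meta", "m_sub", "n_cases", "fma_k", "pred_doses",
            "master_seed", "methods", "risk_models", "alpha_lq", "beta_lq",
            "alpha_linear"),
  groups = c("bounds", "central_doses", "person_years", "n_individuals",
             "n_total"),
  bma = c("prior_sd", "proposal_sd_kappa", "proposal_sd_coef",
          "proposal_sd_lambda", "lambda_block", "n_chains", "n_burnin",
          "n_keep", "bgr_threshold"),
  scenario = c("berkson_shared", "berkson_unshared", "classical_shared",
               "classical_unshared"))

#' Read a study configuration from a steering file
#'
#' Parses the plain-text steering dialect documented in the package (see
#' the methods vignette): `[study]`, `[groups]`, `[bma]` and
#' `[scenario NAME]` sections of `key = value` lines. Unset fields fall
#' back to the [study_config()] defaults; unknown keys are rejected with
#' the offending line number. Error magnitudes may be written as
#' percentages (`berkson_shared = 50%`) or proportions (`0.5`).
#'
#' @param path path to the steering file.
#' @return a [study_config()].
#' @export
read_steering <- function(path) {
  if (!file.exists(path)) stop("steering file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  section <- NULL; scen_name <- NULL
  vals <- list(study = list(), groups = list(), bma = list())
  scen_vals <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      hdr <- trimws(sub("^\\[(.*)\\]$", "\\1", ln))
      if (grepl("^scenario\\s+", hdr)) {
        section <- "scenario"
        scen_name <- trimws(sub("^scenario\\s+", "", hdr))
        scen_vals[[scen_name]] <- list()
      } else if (hdr %in% c("study", "groups", "bma")) {
        section <- hdr
      } else {
        stop(sprintf("line %d: unknown section '[%s]'", i, hdr),
             call. = FALSE)
      }
      next
    }
    if (!grepl("=", ln)) {
      stop(sprintf("line %d: expected 'key = value'", i), call. = FALSE)
    }
    if (is.null(section)) {
      stop(sprintf("line %d: key outside any section", i), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    value <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% steering_keys[[section]]) {
      stop(sprintf("line %d: unknown key '%s' in section [%s]",
                   i, key, section), call. = FALSE)
    }
    entry <- list(value = value, line = i)
    if (section == "scenario") {
      scen_vals[[scen_name]][[key]] <- entry
    } else {
      vals[[section]][[key]] <- entry
    }
  }

  num1 <- function(sec, key, default) {
    e <- vals[[sec]][[key]]
    if (is.null(e)) return(default)
    parse_value_num(e$value, e$line)
  }
  chr <- function(sec, key, default) {
    e <- vals[[sec]][[key]]
    if (is.null(e)) return(default)
    parse_value_chr(e$value)
  }

  grp_args <- list()
  for (key in c("central_doses", "person_years", "n_individuals", "n_total")) {
    v <- num1("groups", key, NULL)
    if (!is.null(v)) grp_args[[key]] <- v
  }
  bounds <- chr("groups", "bounds", NULL)
  if (!is.null(bounds)) grp_args$bounds <- bounds
  groups <- do.call(dose_group_spec, grp_args)

  scenarios <- if (length(scen_vals)) {
    lapply(scen_vals, function(sv) {
      args <- lapply(sv, function(e) parse_value_num(e$value, e$line))
      do.call(error_config, args)
    })
  } else {
    default_scenarios()
  }

  forms <- chr("study", "risk_models", c("linear-quadratic", "linear"))
  risk_models <- lapply(forms, function(fm) {
    if (fm == "linear") {
      risk_model_spec("linear", alpha = num1("study", "alpha_linear", 3))
    } else {
      risk_model_spec("linear-quadratic",
                      alpha = num1("study", "alpha_lq", 0.25),
                      beta = num1("study", "beta_lq", 2))
    }
  })

  bma_args <- lapply(setNames(nm = steering_keys$bma), function(key) {
    e <- vals$bma[[key]]
    if (is.null(e)) NULL else parse_value_num(e$value, e$line)
  })
  bma <- do.call(bma_settings, Filter(Negate(is.null), bma_args))

  study_config(n_meta = num1("study", "n_meta", 500),
               m_sub = num1("study", "m_sub", 1000),
               n_cases = num1("study", "n_cases", 250),
               scenarios = scenarios,
               risk_models = risk_models,
               methods = chr("study", "methods", doserr_methods()),
               groups = groups, bma = bma,
               fma_k = num1("study", "fma_k", 100),
               pred_doses = num1("study", "pred_doses", c(0.1, 1)),
               master_seed = num1("study", "master_seed", 1))
}

#' Write a study configuration as a steering file
#'
#' Inverse of [read_steering()]: emits the configuration in the steering
#' dialect so that write-then-read round-trips.
#'
#' @param config a [study_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_steering <- function(config, path) {
  num <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = ", ")
  ln <- c("[study]",
          sprintf("n_meta = %s", num(config$n_meta)),
          sprintf("m_sub = %s", num(config$m_sub)),
          sprintf("n_cases = %s", num(config$n_cases)),
          sprintf("fma_k = %s", num(config$fma_k)),
          sprintf("pred_doses = %s", num(config$pred_doses)),
          sprintf("master_seed = %s", num(config$master_seed)),
          sprintf("methods = %s", paste(config$methods, collapse = ", ")),
          sprintf("risk_models = %s",
                  paste(vapply(config$risk_models, `[[`, character(1),
                               "form"), collapse = ", ")))
  for (r in config$risk_models) {
    if (r$form == "linear") {
      ln <- c(ln, sprintf("alpha_linear = %s", num(r$alpha)))
    } else {
      ln <- c(ln, sprintf("alpha_lq = %s", num(r$alpha)),
              sprintf("beta_lq = %s", num(r$beta)))
    }
  }
  g <- config$groups
  ln <- c(ln, "", "[groups]",
          sprintf("bounds = %s", paste(g$bounds, collapse = ", ")),
          sprintf("central_doses = %s", num(g$central_doses)),
          sprintf("person_years = %s", num(g$person_years)),
          sprintf("n_individuals = %s", num(g$n_individuals)))
  b <- config$bma
  ln <- c(ln, "", "[bma]",
          sprintf("prior_sd = %s", num(b$prior_sd)),
          sprintf("proposal_sd_kappa = %s", num(b$proposal_sd_kappa)),
          sprintf("proposal_sd_coef = %s", num(b$proposal_sd_coef)),
          sprintf("proposal_sd_lambda = %s", num(b$proposal_sd_lambda)),
          sprintf("lambda_block = %s", num(b$lambda_block)),
          sprintf("n_chains = %s", num(b$n_chains)),
          sprintf("n_burnin = %s", num(b$n_burnin)),
          sprintf("n_keep = %s", num(b$n_keep)),
          sprintf("bgr_threshold = %s", num(b$bgr_threshold)))
  for (nm in names(config$scenarios)) {
    s <- config$scenarios[[nm]]
    ln <- c(ln, "", sprintf("[scenario %s]", nm),
            sprintf("berkson_shared = %s", num(s$berkson_shared)),
            sprintf("berkson_unshared = %s", num(s$berkson_unshared)),
            sprintf("classical_shared = %s", num(s$classical_shared)),
            sprintf("classical_unshared = %s", num(s$classical_unshared)))
  }
  writeLines(ln, path)
  invisible(path)
}
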