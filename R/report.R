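# Pipeline orchestration and publication-shaped tables.

#' Run the full simulate/prepare/correlate/fit pipeline
#'
#' Executes the analysis end to end from a single configuration: simulate a
#' twin cohort (or read one from CSV), ascertain, residualise and ordinalise
#' the endophenotype, estimate the constrained polychoric correlation
#' structure, and fit the requested Cholesky models.  Writes a
#' sample-description table, a correlation table, a model table per fitted
#' model, and a machine-readable JSON bundle with every estimate, interval,
#' log-likelihood and the full provenance (config hash, seed, package
#' version).  Reruns with the same config and seed reproduce the stochastic
#' outputs bit-identically.
#'
#' @param config a named list, or path to a YAML/JSON file.  Recognised
#'   fields (defaults in parentheses): `input` (path to a twin CSV; if absent
#'   a cohort is simulated), `simulate` = list with `h2_bv`, `c2_bv`,
#'   `e2_bv`, `r_g`, `r_c`, `r_e`, `n_mz`, `n_dz`, `scheme`
#'   (`"population"`), `seed` (1), `prevalence` (0.01), `k` (5),
#'   `fixed_sz` (h2 .81, c2 .11, e2 .08), `models` (`"ACE"`),
#'   `ci` (FALSE), `covariates` (site, sex, age, icv), `output_dir`.
#' @param output_dir overrides `config$output_dir`.
#' @return Invisibly, a list with the data, fitted objects and the paths of
#'   the written files.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- list(prevalence = 0.01, k = 5, seed = 1,
              fixed_sz = c(h2 = 0.81, c2 = 0.11, e2 = 0.08),
              models = "ACE", ci = FALSE,
              covariates = c("site", "sex", "age", "icv"),
              output_dir = "twinace-report")
  cfg <- modifyList(def, config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(cfg[setdiff(names(cfg), "output_dir")])
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(cfg$input)) {
      data <- read_twin_csv(cfg$input)
    } else {
      sim <- modifyList(list(h2_bv = 0.5, c2_bv = 0, e2_bv = 0.5,
                             r_g = 0, r_c = 0, r_e = 0,
                             n_mz = 2000, n_dz = 2000,
                             scheme = "population"), cfg$simulate %||% list())
      paths <- twin_paths_from_components(
        sim$h2_bv, sim$c2_bv, sim$e2_bv, sim$r_g, sim$r_c, sim$r_e,
        h2_sz = cfg$fixed_sz[["h2"]], c2_sz = cfg$fixed_sz[["c2"]],
        e2_sz = cfg$fixed_sz[["e2"]])
      data <- simulate_twins(paths, sim$n_mz, sim$n_dz, cfg$prevalence,
                             seed = cfg$seed)
      if (sim$scheme != "population")
        data <- ascertain(data, scheme = sim$scheme, seed = cfg$seed + 1L)
    }
    stage <- "prep"
    data <- prep_bv(data, k = cfg$k, covariates = cfg$covariates)
    stage <- "polychoric"
    pc <- twin_polychoric(data, prevalence = cfg$prevalence, ci = cfg$ci)
    stage <- "fit"
    fits <- lapply(cfg$models, function(m)
      twin_ace(data, prevalence = cfg$prevalence, fixed_sz = cfg$fixed_sz,
               model = m, ci = cfg$ci))
    names(fits) <- cfg$models
    list(data = data, polychoric = pc, fits = fits)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  # write outputs
  od <- cfg$output_dir
  files <- c(
    sample = file.path(od, "sample_description.csv"),
    correlations = file.path(od, "correlations.csv"),
    report = file.path(od, "report.json"))
  write.csv(format_table(res$data, "table1"), files["sample"],
            row.names = FALSE)
  write.csv(format_table(res$polychoric, "table2"), files["correlations"],
            row.names = FALSE)
  model_tabs <- list()
  for (m in names(res$fits)) {
    f <- file.path(od, paste0("model_", m, ".csv"))
    tab <- format_table(res$fits[[m]], "table3")
    write.csv(tab, f, row.names = FALSE)
    files[paste0("model_", m)] <- f
    model_tabs[[m]] <- tab
  }
  bundle <- list(
    provenance = list(config = cfg[setdiff(names(cfg),
                                           c("fixed_sz", "output_dir"))],
                      fixed_sz = as.list(cfg$fixed_sz),
                      config_hash = cfg_hash, seed = cfg$seed,
                      package_version = as.character(utils::packageVersion("twinace")),
                      constants = list(sz_r_mz = 0.92, sz_r_dz = 0.515,
                                       prevalence = cfg$prevalence)),
    polychoric = list(estimate = as.list(res$polychoric$estimate),
                      ci = if (!is.null(res$polychoric$ci))
                        apply(res$polychoric$ci, 1, as.list, simplify = FALSE),
                      thresholds = res$polychoric$thresholds$bv_thresholds,
                      loglik = res$polychoric$loglik),
    models = lapply(res$fits, function(f) list(
      model = f$model, loglik = f$loglik,
      paths = as.list(unclass(f$paths)),
      solution = unclass(f$solution),
      ci = if (!is.null(f$ci)) apply(f$ci, 1, as.list, simplify = FALSE),
      convergence = f$convergence)))
  jsonlite::write_json(bundle, files["report"], auto_unbox = TRUE,
                       digits = 12, pretty = TRUE, na = "null")
  message("pipeline complete; outputs in ", od)
  invisible(c(res, list(files = files, config = cfg)))
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Format results as publication-shaped tables
#'
#' Renders results in the layout of the standard twin-study report tables:
#' sample description (counts by site, zygosity and group), the constrained
#' polychoric correlation table, or the standardized bivariate model table.
#' Correlations and variance proportions are rounded to two decimals with the
#' leading zero dropped, intervals in parentheses, signed zeros normalised,
#' and a footnote marker on quantities whose interval excludes zero.
#'
#' @param results for `"table1"` a data frame of records; for `"table2"` a
#'   `"twin_polychoric"` fit; for `"table3"` a `"twin_ace"` fit.
#' @param style `"table1"`, `"table2"` or `"table3"`.
#' @return A `data.frame` ready for `write.csv`.
#' @export
format_table <- function(results, style = c("table1", "table2", "table3")) {
  style <- match.arg(style)
  switch(style,
    table1 = format_sample_table(results),
    table2 = format_correlation_table(results),
    table3 = format_model_table(results))
}

format_sample_table <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"group" %in% names(data)) {
    aff <- tapply(data$affected, data$pair_id, sum)
    nm <- tapply(data$affected, data$pair_id, length)
    grp <- ifelse(aff >= 2, "concordant", ifelse(aff == 1, "discordant",
                                                 "control"))
    data$group <- grp[as.character(data$pair_id)]
  }
  key <- data[c("site", "zygosity", "group")]
  agg <- stats::aggregate(list(n = rep(1L, nrow(data))), key, sum)
  aff <- stats::aggregate(list(n_affected = data$affected), key, sum)
  out <- merge(agg, aff, by = c("site", "zygosity", "group"))
  out <- out[order(out$site, out$zygosity, out$group), ]
  rownames(out) <- NULL
  out
}

# ".76" / "-.22" style: two decimals, no leading zero, no signed zero
paper_num <- function(x, digits = 2) {
  if (is.na(x)) return("undef")
  x <- round(x, digits)
  if (x == 0) x <- 0   # normalise -0
  s <- sprintf(paste0("%.", digits, "f"), x)
  sub("^(-?)0\\.", "\\1.", s)
}

paper_ci <- function(est, lo, hi) {
  marker <- if (!is.na(lo) && !is.na(hi) && (lo > 0 || hi < 0)) "*" else ""
  if (is.na(lo)) return(paste0(paper_num(est), marker))
  sprintf("%s (%s to %s)%s", paper_num(est), paper_num(lo), paper_num(hi),
          marker)
}

format_correlation_table <- function(fit) {
  stopifnot(inherits(fit, "twin_polychoric"))
  est <- fit$estimate
  ci <- fit$ci
  g <- function(nm) {
    if (!is.null(ci) && nm %in% rownames(ci))
      paper_ci(est[nm], ci[nm, 1], ci[nm, 2])
    else paper_num(est[nm])
  }
  data.frame(
    within_member_cross_trait = g("r_within"),
    cross_member_within_trait_MZ = g("r_bv_mz"),
    cross_member_within_trait_DZ = g("r_bv_dz"),
    cross_member_cross_trait_MZ = g("r_cross_mz"),
    cross_member_cross_trait_DZ = g("r_cross_dz"),
    sz_r_MZ_fixed = paper_num(fit$structure$r_sz_mz, 3),
    sz_r_DZ_fixed = paper_num(fit$structure$r_sz_dz, 3))
}

format_model_table <- function(fit) {
  stopifnot(inherits(fit, "twin_ace"))
  sol <- fit$solution
  ci <- fit$ci
  g <- function(nm, val) {
    if (!is.null(ci) && nm %in% rownames(ci))
      paper_ci(val, ci[nm, 1], ci[nm, 2])
    else paper_num(val)
  }
  data.frame(
    h2_bv = g("h2_bv", sol$h2_bv), c2_bv = g("c2_bv", sol$c2_bv),
    e2_bv = g("e2_bv", sol$e2_bv),
    r_g = g("r_g", sol$r_g), r_c = g("r_c", sol$r_c),
    r_e = g("r_e", sol$r_e), r_ph = g("r_ph", sol$r_ph),
    r_ph_a = g("r_ph_a", sol$r_ph_a), r_ph_c = g("r_ph_c", sol$r_ph_c),
    r_ph_e = g("r_ph_e", sol$r_ph_e),
    model = fit$model)
}

#' Cross-twin scatter of the endophenotype by zygosity
#'
#' Plots twin 1 against twin 2 endophenotype values separately for MZ and DZ
#' pairs, the visual check that a steeper MZ than DZ regression indicates
#' genetic contribution to variance.
#'
#' @param data long-format twin data with `bv`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_twin_pairs <- function(data, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (z in c("MZ", "DZ")) {
    d <- data[data$zygosity == z, ]
    cnt <- table(d$pair_id)
    d <- d[as.character(d$pair_id) %in% names(cnt)[cnt == 2], ]
    d <- d[order(d$pair_id, d$member), ]
    i1 <- seq(1, nrow(d), by = 2)
    x <- d$bv[i1]; y <- d$bv[i1 + 1]
    graphics::plot(x, y, xlab = "twin 1", ylab = "twin 2",
                   main = sprintf("%s pairs (r = %.2f)", z, stats::cor(x, y)),
                   ...)
    graphics::abline(stats::lm(y ~ x), col = 2)
  }
  invisible(data)
}
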