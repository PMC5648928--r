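# Synthetic reference curves: the clinical Kaplan-Meier data the cascade was
# designed against are external publications, so the fitting stages are
# exercised offline by parameter recovery on curves generated from known
# population parameters with fixed seeds.

REFERENCE_SCENARIOS <- data.frame(
  name = c("untreated_I", "untreated_II", "untreated_IIIA",
           "untreated_IIIB", "untreated_IV",
           "rt_only_III", "scrt_III", "ccrt_III"),
  scenario = c(rep("untreated", 5), "rt_only", "scrt", "ccrt"),
  stage = c("I", "II", "IIIA", "IIIB", "IV", NA, NA, NA),
  stringsAsFactors = FALSE)

#' Generate the synthetic reference curve set
#'
#' Simulates the eight reference scenarios (untreated curves for each stage,
#' a radiation-only stage III curve, and sequential/concurrent
#' chemoradiation stage III curves) from a known parameter set, and
#' optionally writes them as monthly CSV curves plus a YAML manifest
#' recording the generating parameters and seed. Regeneration with the same
#' arguments is byte-identical.
#'
#' @param dists Generating [population_distributions()].
#' @param n_per_curve Patients per curve (>= 100).
#' @param master_seed Seed from which every scenario's streams derive.
#' @param dir Output directory, or `NULL` to skip writing.
#' @param config A [sim_config()].
#' @return Named list of `survival_curve`s, invisibly when writing.
#' @export
generate_reference_curves <- function(dists = population_distributions(),
                                      n_per_curve = 1e4,
                                      master_seed = 4242L,
                                      dir = NULL,
                                      config = sim_config()) {
  stopifnot(n_per_curve >= 100)
  curves <- list()
  for (i in seq_len(nrow(REFERENCE_SCENARIOS))) {
    sc <- REFERENCE_SCENARIOS[i, ]
    curves[[sc$name]] <- .scenario_curve(
      dists, sc$scenario,
      stage = if (is.na(sc$stage)) NULL else sc$stage,
      n = n_per_curve, seed = master_seed, config = config)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(curves))
      write_survival_csv(curves[[nm]], file.path(dir, paste0(nm, ".csv")))
    manifest <- list(
      master_seed = as.integer(master_seed),
      n_per_curve = as.integer(n_per_curve),
      parameters = list(
        volume = lapply(seq_len(nrow(dists$volume)), function(j)
          as.list(dists$volume[j, ])),
        rho_mu = dists$rho_mu, rho_sigma = dists$rho_sigma,
        alpha_mu = dists$alpha_mu, alpha_sigma = dists$alpha_sigma,
        correlation = dists$correlation,
        beta_c_mu = dists$beta_c_mu, beta_c_sigma = dists$beta_c_sigma,
        carrying_capacity_diameter = dists$carrying_capacity_diameter,
        delay_min = dists$delay_min, delay_max = dists$delay_max))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    return(invisible(curves))
  }
  curves
}

#' Read a reference curve set from a directory
#'
#' @param dir Directory written by [generate_reference_curves()].
#' @return Named list of `survival_curve`s; the manifest (if present) is
#'   attached as attribute `"manifest"`.
#' @export
read_reference_curves <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no curve CSVs in ", dir)
  curves <- lapply(files, read_survival_csv)
  names(curves) <- sub("\\.csv$", "", basename(files))
  mf <- file.path(dir, "manifest.yaml")
  if (file.exists(mf)) attr(curves, "manifest") <- yaml::read_yaml(mf)
  curves
}

#' Write / read a population parameter set as structured text
#'
#' YAML serialization mirroring the population parameter table
#' field-for-field.
#'
#' @param dists A [population_distributions()].
#' @param path File path.
#' @return `write_population_yaml` returns `path` invisibly;
#'   `read_population_yaml` returns a [population_distributions()].
#' @export
write_population_yaml <- function(dists, path) {
  doc <- list(
    volume = lapply(seq_len(nrow(dists$volume)), function(j)
      as.list(dists$volume[j, ])),
    rho_mu = dists$rho_mu, rho_sigma = dists$rho_sigma,
    alpha_mu = dists$alpha_mu, alpha_sigma = dists$alpha_sigma,
    correlation = dists$correlation,
    beta_c_mu = dists$beta_c_mu, beta_c_sigma = dists$beta_c_sigma,
    carrying_capacity_diameter = dists$carrying_capacity_diameter,
    delay_min = dists$delay_min, delay_max = dists$delay_max)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_population_yaml
#' @export
read_population_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  vol <- do.call(rbind, lapply(doc$volume, function(v)
    data.frame(stage = v$stage, mu = v$mu, sigma = v$sigma,
               lower = v$lower, upper = v$upper)))
  population_distributions(
    volume = vol,
    rho_mu = doc$rho_mu, rho_sigma = doc$rho_sigma,
    alpha_mu = doc$alpha_mu, alpha_sigma = doc$alpha_sigma,
    correlation = doc$correlation,
    beta_c_mu = doc$beta_c_mu, beta_c_sigma = doc$beta_c_sigma,
    carrying_capacity_diameter = doc$carrying_capacity_diameter,
    delay_min = doc$delay_min, delay_max = doc$delay_max)
}
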