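#' @title Tidy exports and run manifests
#' @name reporting
NULL

#' Tidy long-format view of a simulation result
#'
#' @param result a `sim_result`
#' @return data.frame with columns `time_h`, `variable`, `value`;
#'   variables cover plasma (ng/mL), tissues (ng/mL), luminal dissolved
#'   concentrations (mg/mL), tubule segment concentrations (ng/mL) and
#'   the cumulative accumulators (mg)
#' @export
sim_tidy <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  t <- result$time
  blocks <- list(
    data.frame(time_h = t, variable = "plasma_ng_ml",
               value = result$plasma_concentration))
  for (nm in colnames(result$tissue_concentration)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      time_h = t, variable = paste0("tissue_", nm, "_ng_ml"),
      value = result$tissue_concentration[, nm])
  }
  for (nm in colnames(result$luminal_dissolved)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      time_h = t, variable = paste0("lumen_", nm, "_mg_ml"),
      value = result$luminal_dissolved[, nm])
  }
  for (nm in colnames(result$tubule_drug)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      time_h = t, variable = paste0("tubule_", nm, "_ng_ml"),
      value = result$tubule_drug[, nm])
  }
  for (nm in c("cumulative_urinary_excretion",
               "cumulative_hepatic_elimination", "cumulative_fecal",
               "cumulative_absorbed", "cumulative_gut_extracted")) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      time_h = t, variable = paste0(nm, "_mg"), value = result[[nm]])
  }
  do.call(rbind, blocks)
}

#' JSON-ready summary of a simulation
#'
#' @param result a `sim_result`
#' @return list with exposure metrics and disposition fractions
#' @export
sim_summary <- function(result) {
  pk <- nca_sim(result)
  dose <- result$spec$regimen$dose_mg * result$spec$regimen$n_doses
  n <- length(result$time)
  list(compound = result$spec$compound$name,
       dose_mg = result$spec$regimen$dose_mg,
       n_doses = result$spec$regimen$n_doses,
       auc_0_t_ng_h_ml = pk$auc_0_t, auc_0_inf_ng_h_ml = pk$auc_0_inf,
       cmax_ng_ml = pk$cmax, tmax_h = pk$tmax,
       urinary_fraction = result$cumulative_urinary_excretion[n] / dose,
       fecal_fraction = result$cumulative_fecal[n] / dose,
       hepatic_fraction = result$cumulative_hepatic_elimination[n] / dose,
       mass_balance_residual = result$mass_balance_residual)
}

#' Write a run manifest next to generated artifacts
#'
#' Records the configuration hash, package version and seed so that a
#' run can be reproduced exactly; re-running the same manifest reproduces
#' the artifacts byte for byte.
#'
#' @param config list describing the run (any JSON-serializable content)
#' @param dir output directory
#' @param seed the seed the run used
#' @return (invisibly) the manifest list
#' @export
write_manifest <- function(config, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  manifest <- list(config = config,
                   config_hash = unname(tools::md5sum(tmp)),
                   package_version = as.character(
                     utils::packageVersion("sgltsim")),
                   seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
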