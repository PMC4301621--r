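# Scenario orchestration: config-driven runs with manifests, and the
# consolidated multi-section report.

#' Resolve a model argument
#'
#' Accepts a \code{metabolic_model}, the string \code{"mini-alpina"} (the
#' bundled synthetic model), a path to an SBML file (.xml/.sbml) or a
#' tabular bundle directory.
#' @param x model, keyword or path.
#' @export
resolve_model <- function(x) {
  if (inherits(x, "metabolic_model")) return(x)
  if (identical(x, "mini-alpina") || identical(x, "mini_alpina"))
    return(mini_alpina()$model)
  if (dir.exists(x)) return(read_tabular_model(x))
  if (file.exists(x)) return(read_sbml(x))
  stop("cannot resolve model: ", x)
}

resolve_medium <- function(x, glucose_uptake = 0.8) {
  if (is.null(x) || identical(x, "none")) return(NULL)
  if (inherits(x, "growth_medium")) return(x)
  if (identical(x, "MG")) return(medium_mg(glucose_uptake))
  if (identical(x, "YE")) return(medium_ye(glucose_uptake))
  if (file.exists(x)) return(read_medium(x))
  stop("cannot resolve medium: ", x)
}

#' Run one analysis scenario
#'
#' Executes a named analysis on a model under a medium, writing result
#' tables and a reproducibility manifest to \code{out_dir}. The manifest
#' (inputs, parameters, package version) is written before any solving.
#'
#' @param config named list (or path to a JSON file) with fields:
#'   \code{analysis} (one of growth, production, fva, robustness,
#'   essentiality, sources, moma, cofactor_report, gaps), \code{model}
#'   (keyword/path, see \code{\link{resolve_model}}), \code{medium}
#'   (\code{"MG"}, \code{"YE"}, a file path or \code{"none"}), and
#'   analysis-specific fields: \code{objective}, \code{growth_rate},
#'   \code{knockout_genes}, \code{scan} (list: exchange, values),
#'   \code{metabolite}, \code{threshold}, \code{uptake},
#'   \code{candidates}, \code{seed}.
#' @param out_dir output directory (created).
#' @return list with \code{status} and analysis-specific results,
#'   invisibly.
#' @export
run_scenario <- function(config, out_dir = config$out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  analyses <- c("growth", "production", "fva", "robustness", "essentiality",
                "sources", "moma", "cofactor_report", "gaps")
  if (is.null(config$analysis) || !(config$analysis %in% analyses))
    stop("config$analysis must be one of: ", paste(analyses, collapse = ", "))
  if (is.null(out_dir)) stop("no output directory configured")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  set.seed(seed)
  manifest <- list(analysis = config$analysis,
                   model = if (is.character(config$model)) config$model else "in-memory",
                   medium = if (is.character(config$medium)) config$medium else
                     if (is.null(config$medium)) "none" else config$medium$name,
                   parameters = config[setdiff(names(config),
                                               c("analysis", "model", "medium", "out_dir"))],
                   package_version = as.character(utils::packageVersion("oleoflux")),
                   seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  model <- resolve_model(config$model)
  med <- resolve_medium(config$medium,
                        glucose_uptake = config$glucose_uptake %||% 0.8)
  model_m <- apply_medium(model, med)
  threshold <- config$threshold %||% 1e-6
  res <- switch(config$analysis,
    growth = {
      sol <- solve_fba(model_m, objective = config$objective %||% model$objective)
      write_flux_table(sol, file.path(out_dir, "fluxes.tsv"))
      list(status = sol$status, growth = sol$objective_value)
    },
    production = {
      sol <- solve_fba_fixed_growth(model_m,
                                    growth_rate = config$growth_rate %||% 0.03,
                                    objective = config$objective)
      write_flux_table(sol, file.path(out_dir, "fluxes.tsv"))
      list(status = sol$status, production = sol$objective_value)
    },
    fva = {
      r <- fva(model_m, reaction_ids = config$reactions %||% rxn_ids(model),
               fraction_of_optimum = config$fraction %||% 1.0)
      write_flux_table(r, file.path(out_dir, "fva.tsv"))
      list(status = "optimal", fva = r)
    },
    robustness = {
      sc <- config$scan
      values <- sc$values %||% seq(sc$from, sc$to, by = sc$step)
      r <- robustness_scan(model_m, sc$exchange, values,
                           objective = config$objective,
                           min_growth = config$min_growth)
      utils::write.table(data.frame(parameter = r$parameter,
                                    objective = r$objective_value),
                         file.path(out_dir, "robustness.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(status = "optimal", curve = r)
    },
    essentiality = {
      r <- single_gene_deletion(model, medium = med,
                                threshold = config$threshold %||% 0.01)
      write_flux_table(r, file.path(out_dir, "essentiality.tsv"))
      jsonlite::write_json(list(essential = sum(r$call == "essential"),
                                total = nrow(r),
                                threshold = attr(r, "threshold"),
                                wild_type_growth = attr(r, "wild_type_growth")),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(status = "optimal", report = r)
    },
    sources = {
      r <- substrate_utilization_screen(model, med, config$candidates,
                                        remove = config$remove %||% character(0),
                                        uptake = config$uptake %||% 1.0)
      write_flux_table(r, file.path(out_dir, "sources.tsv"))
      list(status = "optimal", screen = r)
    },
    moma = {
      ref <- solve_fba_fixed_growth(model_m, config$growth_rate %||% 0.03,
                                    objective = config$objective)
      sol <- solve_moma(model_m, ref, knockout_genes = config$knockout_genes)
      write_flux_table(sol, file.path(out_dir, "moma_fluxes.tsv"))
      chg <- count_changed_reactions(ref, sol, threshold)
      list(status = sol$status, distance = sol$distance,
           changed = chg$count, reference = ref, moma = sol)
    },
    cofactor_report = {
      ref <- solve_fba(model_m)
      prod <- solve_fba_fixed_growth(model_m, config$growth_rate %||% 0.03,
                                     objective = config$objective)
      r <- differential_flux_report(model, config$metabolite, ref, prod,
                                    threshold = threshold)
      write_flux_table(r, file.path(out_dir, "cofactor_report.tsv"))
      list(status = "optimal", report = r)
    },
    gaps = {
      r <- find_blocked_metabolites(model, medium = med)
      utils::write.table(
        data.frame(metabolite = r$no_production,
                   root = r$no_production %in% r$root_no_production),
        file.path(out_dir, "gaps.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(status = "optimal", gaps = r)
    })
  jsonlite::write_json(list(analysis = config$analysis, status = res$status,
                            headline = res[[2]]),
                       file.path(out_dir, "result.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consolidated multi-section report
#'
#' Reruns the full scenario suite on a model: (1) growth-rate verification
#' on MG and YE, (2) gene essentiality on MG vs YE, (3) ARA-vs-oxygen
#' robustness, (4) NADPH differential flux between growth and production
#' modes, (5) malic-enzyme knockout under MOMA. Each section records the
#' corresponding published iCY1106 value where one exists, labelled
#' \code{reference}; on any other model those cells read "synthetic".
#'
#' @param model a \code{metabolic_model} (default: the bundled synthetic
#'   model).
#' @param out_dir output directory.
#' @param oxygen_values scan grid for section 3.
#' @return list of section summaries, invisibly.
#' @export
paper_report <- function(model = NULL, out_dir, oxygen_values = seq(0.25, 6, by = 0.25)) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  is_synth <- is.null(model)
  if (is_synth) model <- mini_alpina()$model
  label <- if (is_synth) "synthetic" else "user-model"
  mg <- medium_mg(); ye <- medium_ye()
  sections <- list()

  g_mg <- solve_fba(apply_medium(model, mg))
  g_ye <- solve_fba(apply_medium(model, ye))
  sections$growth <- data.frame(
    medium = c("MG", "YE"), growth = c(g_mg$objective_value, g_ye$objective_value),
    reference_icy1106 = c(NA, 0.0690), label = label)

  ess_mg <- single_gene_deletion(model, mg)
  ess_ye <- single_gene_deletion(model, ye)
  sections$essentiality <- data.frame(
    medium = c("MG", "YE"),
    essential = c(sum(ess_mg$call == "essential"), sum(ess_ye$call == "essential")),
    total = length(model$genes), reference_icy1106 = c(86, 49), label = label)

  ye003 <- apply_medium(model, ye)
  rc <- robustness_scan(ye003, "EX_o2", oxygen_values, objective = "EX_ara",
                        min_growth = 0.03)
  ok <- which(!is.na(rc$objective_value))
  sections$oxygen <- data.frame(
    optimum_uptake = if (length(ok)) rc$parameter[ok[which.max(rc$objective_value[ok])]] else NA,
    reference_icy1106 = 2.0, label = label)
  utils::write.table(data.frame(o2 = rc$parameter, ara = rc$objective_value),
                     file.path(out_dir, "oxygen_robustness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  grow_sol <- solve_fba_fixed_growth(ye003, 0.06, objective = "EX_ara")
  prod_sol <- solve_fba_fixed_growth(ye003, 0.03, objective = "EX_ara")
  nad <- differential_flux_report(model, "nadph[c]", grow_sol, prod_sol,
                                  labels = c("growth", "production"))
  sections$nadph <- data.frame(nadph_reactions = nrow(nad),
                               changed = sum(nad$changed),
                               reference_icy1106_changed = 53, label = label)
  write_flux_table(nad, file.path(out_dir, "nadph_differential.tsv"))

  ko <- knockout_gene(model, "gME")
  momasol <- solve_moma(ko, prod_sol)
  ara0 <- prod_sol$flux[["EX_ara"]]
  ara1 <- momasol$flux[["EX_ara"]]
  sections$moma_me <- data.frame(
    ara_wild_type = ara0, ara_me_knockout = ara1,
    percent_change = flux_ratio_change(ara0, ara1),
    reference_icy1106 = -38.28, label = label)

  for (nm in names(sections))
    utils::write.table(sections[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sections, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(sections)
}
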