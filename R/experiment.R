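## Configuration-driven experiments: phantom -> plan -> shift battery ->
## report bundle, with a single seed governing every random draw.

.default_config <- function() {
  list(seed = 1L, n_phantoms = 1L, phantom = list(), species = "carbon",
       mode = "mc", beams = "LR", prescription = list(dose = 60,
                                                      fractions = 20),
       constraints = "default", magnitudes = c(1, 2),
       thresholds = c(v95 = 1, hi = 1, dose = 2), out = NULL,
       control = list(), dvh_structures = c("CTV", "PTV"))
}

#' Read and validate a run configuration
#'
#' Configurations are flat YAML (or an R list) with the keys of
#' `.default_config()`: seed, number of phantoms, phantom spec overrides,
#' species, optimization mode, beam setup (`"LR"`, `"ROB"` or a list of
#' direction vectors), prescription, constraints (`"default"`, `"none"` or a
#' list), shift magnitudes, histogram thresholds and output directory.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, config)
  if (!cfg$species %in% c("carbon", "proton")) stopf("invalid species")
  if (!cfg$mode %in% c("uc", "sc", "mc")) stopf("invalid mode")
  if (length(cfg$magnitudes)) check_numeric(cfg$magnitudes, "magnitudes",
                                            positive = TRUE)
  check_numeric(cfg$seed, "seed", 1)
  if (cfg$n_phantoms < 1) stopf("n_phantoms must be >= 1")
  cfg
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

.write_csv_hashed <- function(df, file, hash) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# config %s", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(file)
}

.resolve_beams <- function(cfg, grid, structures) {
  if (is.character(cfg$beams)) {
    if (cfg$beams == "LR") return(lateral_opposed_beams(cfg$species))
    if (cfg$beams == "ROB") {
      cand <- candidate_directions()
      sel <- select_robust_setup(grid, structures$masks$CTV, cand)
      return(beams_from_candidates(sel, cfg$species))
    }
    stopf("beams must be 'LR', 'ROB' or a list of direction vectors")
  }
  lapply(cfg$beams, function(d) beam_setup(as.numeric(d), cfg$species))
}

.resolve_constraints <- function(cfg) {
  if (is.character(cfg$constraints)) {
    if (cfg$constraints == "default") return(default_constraints(cfg$species))
    if (cfg$constraints == "none") return(list())
    stopf("constraints must be 'default', 'none' or a list")
  }
  cfg$constraints
}

#' Run a configuration-driven robustness experiment
#'
#' For each seeded phantom: generate, optimize a plan in the configured mode
#' and beam setup, recompute the dose under every member of the enumerated
#' shift set and collect index deltas. Writes a report bundle (planned-index
#' table, per-shift delta CSV, population-summary JSON, DVH CSVs and a log)
#' to the output directory; identical configuration and seed give
#' byte-identical CSV/JSON outputs.
#'
#' @param config YAML path or list (see [read_run_config()]).
#' @return Invisibly, a list with `indices`, `deltas`, `summary`, `paths`,
#'   and `config_hash`.
#' @export
run_experiment <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$out)) stopf("config must set an output directory 'out'")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg[setdiff(names(cfg), "out")])
  logf <- file.path(cfg$out, "run.log")
  cat(sprintf("pbsrobust %s | R %s | seed %d | config %s\n",
              as.character(utils::packageVersion("pbsrobust")),
              paste(R.version$major, R.version$minor, sep = "."),
              as.integer(cfg$seed), hash), file = logf)
  logmsg <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  shifts <- enumerate_shifts(cfg$magnitudes)
  pres <- do.call(prescription, cfg$prescription)
  indices <- NULL; deltas <- NULL
  dvh_paths <- character(0)
  for (i in seq_len(cfg$n_phantoms)) {
    t0 <- Sys.time()
    spec <- do.call(phantom_spec,
                    modifyList(cfg$phantom,
                               list(seed = as.integer(cfg$seed) + i)))
    ph <- make_skullbase_phantom(spec)
    beams <- .resolve_beams(cfg, ph$grid, ph$structures)
    plan <- optimize_plan(ph$grid, ph$structures, beams, pres,
                          constraints = .resolve_constraints(cfg),
                          mode = cfg$mode, control = cfg$control)
    idx <- cbind(data.frame(case = i), plan$indices)
    indices <- rbind(indices, idx)
    if (nrow(shifts) > 0) {
      db <- cbind(data.frame(case = i), shift_battery(plan, shifts))
      deltas <- rbind(deltas, db)
    }
    for (nm in intersect(cfg$dvh_structures, names(ph$structures$masks))) {
      dvh <- cumulative_dvh(plan$dose, ph$structures$masks[[nm]], pres$dose)
      p <- file.path(cfg$out, sprintf("dvh_case%02d_%s.csv", i, nm))
      .write_csv_hashed(data.frame(dose = dvh$dose, volume = dvh$volume),
                        p, hash)
      dvh_paths <- c(dvh_paths, p)
    }
    logmsg("case %d: %s %s%s plan, %d spots, PTV V95 %.1f%% [%.1f s]",
           i, cfg$species, cfg$mode,
           if (is.character(cfg$beams)) cfg$beams else "", nrow(plan$spots),
           plan$indices$ptv_v95, as.numeric(Sys.time() - t0, units = "secs"))
  }
  paths <- list(indices = file.path(cfg$out, "indices.csv"),
                deltas = file.path(cfg$out, "deltas.csv"),
                summary = file.path(cfg$out, "summary.json"),
                dvh = dvh_paths, log = logf)
  .write_csv_hashed(indices, paths$indices, hash)
  if (is.null(deltas))
    deltas <- data.frame(case = integer(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), magnitude = numeric(0),
                         label = character(0))
  .write_csv_hashed(deltas, paths$deltas, hash)
  summ <- NULL
  if (nrow(deltas) > 0) {
    summ <- aggregate_population(deltas, cfg$thresholds)
    jsonlite::write_json(list(config = hash,
                              summary = as.data.frame(summ)),
                         paths$summary, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(indices = indices, deltas = deltas, summary = summ,
                 paths = paths, config_hash = hash))
}

#' Lateral-opposed versus robust beam setups on a phantom population
#'
#' The package's core experiment: for each seeded heterogeneous phantom,
#' optimize a multiple-field (`mc`) plan with the lateral-opposed setup and
#' one with the heterogeneity-minimizing setup selected by
#' [select_robust_setup()], recompute both under the transverse members of
#' the enumerated shift set (zero LR component) at the given magnitude, and
#' collect CTV coverage/homogeneity deltas per setup.
#'
#' @param n_phantoms Number of seeded phantoms (>= 1).
#' @param species Ion species (one or both).
#' @param seed Base seed; phantom `i` uses `seed + i`.
#' @param phantom Named list of [phantom_spec()] overrides; the default uses
#'   a 44^3 grid at 3 mm with CTV volumes from the lower part of the
#'   clinical range (16-26 cm^3), which keeps the spot count tractable.
#' @param magnitude Shift magnitude (mm) of the transverse probe battery.
#' @param candidates Candidate directions for the robust selection.
#' @param control Optimizer control overrides.
#' @return Data.frame with one row per phantom x species x setup x shift:
#'   seed, species, setup (`"LR"`/`"ROB"`), shift columns and `d_*` deltas.
#' @export
beam_setup_comparison <- function(n_phantoms = 10,
                                  species = c("carbon", "proton"),
                                  seed = 1, phantom = list(),
                                  magnitude = 2,
                                  candidates = candidate_directions(
                                    yaw = seq(0, 60, by = 20),
                                    inclination = seq(-30, 30, by = 30)),
                                  control = list(maxit = 120)) {
  species <- match.arg(species, several.ok = TRUE)
  spec_args <- modifyList(list(shape = c(44, 44, 44), spacing = c(3, 3, 3),
                               ctv_volume_range = c(16, 26)), phantom)
  shifts <- enumerate_shifts(magnitude)
  shifts <- shifts[shifts$x == 0, , drop = FALSE]
  pres <- prescription()
  out <- NULL
  for (i in seq_len(n_phantoms)) {
    ph <- make_skullbase_phantom(
      do.call(phantom_spec, modifyList(spec_args,
                                       list(seed = as.integer(seed) + i))))
    sel <- select_robust_setup(ph$grid, ph$structures$masks$CTV, candidates,
                               max_target_voxels = 200)
    for (sp in species) {
      cons <- default_constraints(sp)
      setups <- list(LR = lateral_opposed_beams(sp),
                     ROB = beams_from_candidates(sel, sp))
      for (nm in names(setups)) {
        plan <- suppressWarnings(
          optimize_plan(ph$grid, ph$structures, setups[[nm]], pres, cons,
                        mode = "mc", control = control))
        db <- shift_battery(plan, shifts)
        out <- rbind(out, cbind(data.frame(seed = seed + i, species = sp,
                                           setup = nm), db))
      }
    }
  }
  out
}

#' Compare two experiment reports with the paired sign test
#'
#' Pairs the per-shift records of two reports by case and shift label,
#' computes the paired differences of the chosen index and applies the exact
#' two-sided sign test.
#'
#' @param report_a,report_b Results of [run_experiment()] (or paths to their
#'   `deltas.csv`).
#' @param index Delta column to compare, e.g. `"d_ctv_v95"`.
#' @return List with the paired `table`, `p_value`, `n` and `significant`.
#' @export
compare_groups <- function(report_a, report_b, index = "d_ctv_v95") {
  load_deltas <- function(r) {
    if (is.character(r)) read.csv(r, comment.char = "#") else r$deltas
  }
  a <- load_deltas(report_a); b <- load_deltas(report_b)
  if (!index %in% names(a) || !index %in% names(b))
    stopf("index '%s' not present in both reports", index)
  key_a <- paste(a$case, a$label); key_b <- paste(b$case, b$label)
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b))
    stopf("reports do not share the same case x shift keys")
  b <- b[match(key_a, key_b), ]
  st <- sign_test(a[[index]], b[[index]])
  tab <- data.frame(case = a$case, label = a$label, a = a[[index]],
                    b = b[[index]], diff = a[[index]] - b[[index]])
  c(list(table = tab, index = index), st)
}
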