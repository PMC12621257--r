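#' Benchmark table of one metric over compounds x methods
#'
#' A rectangular compound-by-method matrix of one metric (Angstrom, eV or
#' percent). Missing cells are `NA` and are excluded from every aggregate.
#'
#' @param values numeric matrix, rows = compounds, cols = methods
#' @param metric_name which quantity the cells hold
#' @return an object of class `benchmark_table`
#' @export
benchmark_table <- function(values, metric_name = "") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("compound_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("method_", seq_len(ncol(values)))
  }
  structure(list(values = values, metric_name = metric_name),
            class = "benchmark_table")
}

#' Per-method average and median of a benchmark table
#'
#' Arithmetic mean and median over compounds, per method, skipping missing
#' cells. For energy shifts set `absolute = TRUE` so the aggregation uses
#' |delta| (the "absolute shift"). Methods with no data are dropped with a
#' warning. The result is sorted ascending by average — for error-like
#' metrics smaller is better; for similarities sort descending yourself.
#'
#' @param table a [benchmark_table()]
#' @param absolute take absolute values before aggregating (default FALSE)
#' @return data.frame with `method`, `average`, `median`, `n`
#' @export
aggregate_methods <- function(table, absolute = FALSE) {
  stopifnot(inherits(table, "benchmark_table"))
  v <- table$values
  if (absolute) v <- abs(v)
  n_ok <- colSums(!is.na(v))
  if (any(n_ok == 0)) {
    warning("excluding method(s) with no data: ",
            paste(colnames(v)[n_ok == 0], collapse = ", "), call. = FALSE)
    v <- v[, n_ok > 0, drop = FALSE]
    n_ok <- n_ok[n_ok > 0]
  }
  out <- data.frame(
    method = colnames(v),
    average = apply(v, 2, mean, na.rm = TRUE),
    median = apply(v, 2, stats::median, na.rm = TRUE),
    n = as.integer(n_ok),
    row.names = NULL
  )
  out[order(out$average), , drop = FALSE]
}

#' Box-plot statistics with the 1.5 x IQR outlier rule
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Points beyond 1.5 x IQR from the quartiles
#' are outliers; the whiskers sit at the extreme non-outlier points.
#'
#' @param values numeric vector, at least one finite value
#' @param coef whisker reach in IQR multiples (default 1.5)
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`
#' @export
boxplot_stats <- function(values, coef = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - coef * iqr
  hi_fence <- q[3] + coef * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    outliers = sort(values[!inside]),
    n = length(values)
  )
}

#' Box-plot statistics per compound group, per method
#'
#' Computes [boxplot_stats()] independently for each group of compounds
#' (e.g. splitting Fe(II) complexes from other oxidation states). Groups
#' with no data for a method are skipped with a warning.
#'
#' @param table a [benchmark_table()]
#' @param groups named list of compound-name vectors (a partition of a
#'   subset of the rows)
#' @param absolute take absolute values first (default FALSE)
#' @return nested list: `result[[group]][[method]]` is a [boxplot_stats()]
#' @export
subgroup_stats <- function(table, groups, absolute = FALSE) {
  stopifnot(inherits(table, "benchmark_table"))
  v <- table$values
  if (absolute) v <- abs(v)
  out <- list()
  for (g in names(groups)) {
    rows <- intersect(groups[[g]], rownames(v))
    if (length(rows) == 0) {
      warning("empty group '", g, "' excluded", call. = FALSE)
      next
    }
    sub <- v[rows, , drop = FALSE]
    out[[g]] <- lapply(stats::setNames(colnames(sub), colnames(sub)),
                       function(m) {
      col <- sub[, m]
      if (all(is.na(col))) return(NULL)
      boxplot_stats(col)
    })
  }
  out
}

#' Run the full structure + spectra benchmark from a manifest
#'
#' The manifest (a YAML file or an equivalent list) declares compounds and
#' methods:
#'
#' ```yaml
#' compounds:
#'   - id: cpd1
#'     window: [1.4, 4.8]        # eV
#'     exp_spectrum: cpd1_exp.txt
#'     ref_structure: cpd1_ref.xyz
#'     solvent: acetonitrile      # metadata only
#'     bond_tolerance: 1.3        # optional
#'     ligand_indices: [2,3,4]    # optional explicit coordination sphere
#'     methods:
#'       methodA: {sticks: cpd1_A.stk, structure: cpd1_A.xyz}
#' spacing_ev: 0.0123984          # optional, defaults to 100 cm^-1
#' ```
#'
#' Paths are resolved relative to the manifest file. Per-item failures are
#' logged as warnings and the affected cells marked missing; the run
#' continues. Output is deterministic given the manifest and files.
#'
#' @param manifest path to a YAML manifest, or the already-parsed list
#'   (then set `base_dir`)
#' @param out_dir optional directory; when given, the similarity and
#'   structure tables are written there as TSV
#' @param base_dir directory for resolving relative paths when `manifest`
#'   is a list
#' @return list with data.frames `similarity` (compound, method, delta_opt,
#'   sigma_opt, fwhm_opt, s_max, window_lo, window_hi, converged) and
#'   `structures` (compound, method, rmse, n_bonds, mue, mse), plus
#'   `aggregates` (per-method summaries of each metric)
#' @export
run_benchmark <- function(manifest, out_dir = NULL, base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  spacing <- manifest$spacing_ev %||% cm1_to_ev(100)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(base_dir, p)

  sim_rows <- list()
  str_rows <- list()
  for (cpd in manifest$compounds) {
    id <- cpd$id
    window <- as.numeric(cpd$window)
    exp_spec <- tryCatch({
      raw <- read_xy_spectrum(resolve(cpd$exp_spectrum), domain = "energy",
                              label = id)
      condition(raw, spacing = spacing, window = window)
    }, error = function(e) {
      warning("compound ", id, ": experimental spectrum failed (",
              conditionMessage(e), ")", call. = FALSE)
      NULL
    })
    ref <- tryCatch(
      read_xyz(resolve(cpd$ref_structure)),
      error = function(e) {
        warning("compound ", id, ": reference structure failed (",
                conditionMessage(e), ")", call. = FALSE)
        NULL
      })
    bonds <- NULL
    if (!is.null(ref)) {
      bonds <- tryCatch({
        if (!is.null(cpd$ligand_indices)) {
          bond_set(ref$metal_index, unlist(cpd$ligand_indices))
        } else {
          detect_metal_bonds(ref, tolerance = cpd$bond_tolerance %||% 1.3)
        }
      }, error = function(e) {
        warning("compound ", id, ": bond detection failed (",
                conditionMessage(e), ")", call. = FALSE)
        NULL
      })
    }
    for (m in names(cpd$methods)) {
      entry <- cpd$methods[[m]]
      if (!is.null(exp_spec) && !is.null(entry$sticks)) {
        row <- tryCatch({
          sticks <- read_stick_spectrum(resolve(entry$sticks),
                                        label = paste(id, m))
          fit <- optimize_similarity(exp_spec, sticks)
          data.frame(compound = id, method = m,
                     delta_opt = fit$delta_opt, sigma_opt = fit$sigma_opt,
                     fwhm_opt = fit$fwhm_opt, s_max = fit$s_max,
                     window_lo = window[1], window_hi = window[2],
                     converged = fit$diagnostics$converged)
        }, error = function(e) {
          warning(id, "/", m, ": similarity failed (",
                  conditionMessage(e), ")", call. = FALSE)
          NULL
        })
        if (!is.null(row)) sim_rows[[length(sim_rows) + 1]] <- row
      }
      if (!is.null(ref) && !is.null(bonds) && !is.null(entry$structure)) {
        row <- tryCatch({
          comp <- read_xyz(resolve(entry$structure))
          met <- structure_metrics(comp, ref, bonds = bonds)
          data.frame(compound = id, method = m, rmse = met$rmse,
                     n_bonds = met$n_bonds, mue = met$mue, mse = met$mse)
        }, error = function(e) {
          warning(id, "/", m, ": structure metrics failed (",
                  conditionMessage(e), ")", call. = FALSE)
          NULL
        })
        if (!is.null(row)) str_rows[[length(str_rows) + 1]] <- row
      }
    }
  }
  similarity_tab <- if (length(sim_rows)) do.call(rbind, sim_rows) else
    data.frame()
  structure_tab <- if (length(str_rows)) do.call(rbind, str_rows) else
    data.frame()

  aggregates <- list()
  if (nrow(structure_tab)) {
    for (metric in c("rmse", "mue", "mse")) {
      tab <- long_to_table(structure_tab, metric)
      aggregates[[metric]] <- aggregate_methods(tab)
    }
  }
  if (nrow(similarity_tab)) {
    aggregates$abs_shift <- aggregate_methods(
      long_to_table(similarity_tab, "delta_opt"), absolute = TRUE)
    agg_s <- aggregate_methods(long_to_table(similarity_tab, "s_max"))
    aggregates$s_max <- agg_s[order(-agg_s$average), , drop = FALSE]
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_stable(similarity_tab, file.path(out_dir, "similarity.tsv"))
    write_tsv_stable(structure_tab, file.path(out_dir, "structures.tsv"))
    for (nm in names(aggregates)) {
      write_tsv_stable(aggregates[[nm]],
                       file.path(out_dir, paste0("aggregate_", nm, ".tsv")))
    }
  }
  list(similarity = similarity_tab, structures = structure_tab,
       aggregates = aggregates)
}

#' Pivot a long result table into a compound x method benchmark table
#'
#' @param df data.frame with `compound`, `method` and the metric column
#' @param metric column name to pivot
#' @return a [benchmark_table()]
#' @export
long_to_table <- function(df, metric) {
  compounds <- sort(unique(df$compound))
  methods <- sort(unique(df$method))
  v <- matrix(NA_real_, length(compounds), length(methods),
              dimnames = list(compounds, methods))
  for (i in seq_len(nrow(df))) {
    v[df$compound[i], df$method[i]] <- df[[metric]][i]
  }
  benchmark_table(v, metric_name = metric)
}

# deterministic TSV writer: fixed significant digits, no row names
write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
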