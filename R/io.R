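# CSV dataset interchange (header `aw,temperature_c,method,branch,
# replicate,xe`, UTF-8, LF), a JSON sidecar carrying the synthetic truth,
# and JSON serialization of fit reports, metrics and rankings.

#' Write a sorption dataset to CSV (plus truth sidecar)
#'
#' Floats are written at full precision with LF line endings. Synthetic
#' datasets also get a `<path>.truth.json` sidecar recording the truth
#' model, parameters, noise and seed.
#'
#' @param data an `isotherm_dataset` or compatible data.frame.
#' @param path output CSV path.
#' @param sidecar write the truth sidecar when truth is present.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, sidecar = TRUE) {
  df <- as.data.frame(data)[, c("aw", "temperature_c", "method", "branch",
                                "replicate", "xe")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("aw,temperature_c,method,branch,replicate,xe", con, sep = "\n",
             useBytes = TRUE)
  lines <- paste(fmt_num(df$aw), fmt_num(df$temperature_c), df$method,
                 df$branch, df$replicate, fmt_num(df$xe), sep = ",")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  tr <- attr(data, "truth")
  if (sidecar && !is.null(tr)) {
    side <- list(
      truth = list(model = tr$spec$name, temp_mode = tr$spec$temp_mode,
                   uses_dummies = tr$spec$uses_dummies,
                   constants = tr$spec$constants,
                   params = as.list(tr$params),
                   noise = list(kind = tr$noise$kind, sd = tr$noise$sd)),
      seed = attr(data, "seed"), provenance = attr(data, "provenance"))
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a sorption dataset from CSV
#'
#' Validates the header, water-activity range, and factor levels (errors
#' name the offending rows); applies the percent-to-decimal conversion if
#' declared; re-attaches a truth sidecar when present.
#'
#' @param path CSV path written by [write_dataset()] or compatible.
#' @param xe_unit `"decimal"` (default) or `"percent"`; percent values
#'   are divided by 100 on ingest.
#' @return an `isotherm_dataset`.
#' @export
read_dataset <- function(path, xe_unit = c("decimal", "percent")) {
  xe_unit <- match.arg(xe_unit)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("aw", "temperature_c", "method", "branch", "replicate", "xe")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_sorb(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
              "sorbfit_schema_error")
  bad <- which(!is.finite(df$aw) | df$aw <= 0 | df$aw >= 1)
  if (length(bad))
    stop_sorb(sprintf("aw outside (0, 1) at row(s): %s",
                      paste(head(bad, 5), collapse = ", ")),
              "sorbfit_schema_error")
  badm <- which(!df$method %in% c("wet", "semidry"))
  if (length(badm))
    stop_sorb(sprintf("unknown method label at row(s): %s",
                      paste(head(badm, 5), collapse = ", ")),
              "sorbfit_schema_error")
  badb <- which(!df$branch %in% c("desorption", "adsorption"))
  if (length(badb))
    stop_sorb(sprintf("unknown branch label at row(s): %s",
                      paste(head(badb, 5), collapse = ", ")),
              "sorbfit_schema_error")
  key <- paste(df$aw, df$temperature_c, df$method, df$branch, df$replicate)
  if (anyDuplicated(key))
    stop_sorb("duplicate (aw, temperature, method, branch, replicate) keys",
              "sorbfit_schema_error")
  if (xe_unit == "percent") df$xe <- df$xe / 100
  out <- structure(df, provenance = "measured",
                   class = c("isotherm_dataset", "data.frame"))
  sidep <- paste0(path, ".truth.json")
  if (file.exists(sidep)) {
    side <- jsonlite::read_json(sidep, simplifyVector = TRUE)
    spec <- model_spec(side$truth$model, temp_mode = side$truth$temp_mode,
                       uses_dummies = isTRUE(side$truth$uses_dummies),
                       lambda = side$truth$constants$lambda,
                       R_w = side$truth$constants$R_w)
    attr(out, "truth") <- list(spec = spec,
                               params = unlist(side$truth$params),
                               noise = noise_model(side$truth$noise$kind,
                                                   side$truth$noise$sd))
    attr(out, "seed") <- side$seed
    attr(out, "provenance") <- side$provenance %||% "synthetic"
  }
  out
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @param level confidence level for the embedded intervals.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, level = 0.95) {
  ci <- tryCatch(confidence_intervals(fit, level), error = function(e) NULL)
  rep <- list(model = fit$spec$name, temp_mode = fit$spec$temp_mode,
              uses_dummies = fit$spec$uses_dummies,
              strategy = fit$strategy,
              params = as.list(fit$params),
              confidence_intervals = ci,
              rms = fit$rms, n_obs = fit$n_obs,
              converged = fit$converged, iterations = fit$iterations)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the per-iteration metrics table to CSV
#' @param metrics metrics data.frame from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("model,iteration,subset,mre_pct,r2_pct,r2adj_pct,n,m", con,
             sep = "\n", useBytes = TRUE)
  lines <- paste(metrics$model, metrics$iteration, metrics$subset,
                 fmt_num(metrics$mre), fmt_num(metrics$r2),
                 fmt_num(metrics$r2adj), metrics$n, metrics$m, sep = ",")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#' @param path CSV path.
#' @return metrics data.frame with in-memory column names.
#' @export
read_metrics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- sub("_pct$", "", names(df))
  df
}

#' Serialize a ranking table to JSON
#' @param ranking a `ranking_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  out <- list(alpha = attr(ranking, "alpha"),
              lsd_mre = attr(ranking, "lsd_mre"),
              lsd_r2adj = attr(ranking, "lsd_r2adj"),
              table = as.data.frame(ranking))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot isotherms with model predictions overlaid
#'
#' One panel per method: observed points by temperature with predicted
#' curves, a reporting convenience for the `report` CLI command.
#'
#' @param data sorption records.
#' @param predict_fun optional `function(df)` returning predictions.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plot_isotherms <- function(data, predict_fun = NULL, main = "") {
  data <- as.data.frame(data)
  methods <- unique(data$method)
  temps <- sort(unique(data$temperature_c))
  cols <- grDevices::hcl.colors(max(3, length(temps)), "Dark 3")
  graphics::par(mfrow = c(1, length(methods)))
  for (m in methods) {
    sub <- data[data$method == m, ]
    graphics::plot(sub$aw, sub$xe, pch = 20, cex = 0.4,
                   col = cols[match(sub$temperature_c, temps)],
                   xlab = "water activity", ylab = "X_e (decimal d.b.)",
                   main = paste(main, m))
    if (!is.null(predict_fun)) {
      for (tc in temps) for (br in unique(sub$branch)) {
        g <- sub[sub$temperature_c == tc & sub$branch == br, ]
        g <- g[order(g$aw), ]
        if (nrow(g)) graphics::lines(g$aw, predict_fun(g), lwd = 1.5,
                                     col = cols[match(tc, temps)])
      }
    }
    graphics::legend("topleft", legend = paste0(temps, " C"), col = cols,
                     pch = 20, bty = "n", cex = 0.8)
  }
  invisible(NULL)
}
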