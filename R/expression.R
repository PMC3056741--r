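# Gene-expression time series: ingestion, per-gene min-max scaling, and
# conversion of expression values into per-reaction bound multipliers
# (time-resolved E-flux).

#' Construct an expression time series
#'
#' @param values numeric matrix, one row per gene (rownames = gene ids),
#'   one column per time point; all values non-negative.
#' @param time_points_h numeric vector of time points in hours (canonically
#'   0, 3, ..., 24: nine samples over 27 h collapsed onto one cycle).
#' @return An `expression_series`.
#' @export
expression_series <- function(values, time_points_h) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must carry unique gene ids as rownames")
  if (ncol(values) != length(time_points_h))
    stop("number of columns (", ncol(values),
         ") disagrees with time points (", length(time_points_h), ")")
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("time points must be strictly increasing")
  if (anyNA(values)) stop("missing expression values")
  if (any(values < 0)) stop("negative expression values")
  colnames(values) <- paste0("ZT", time_points_h)
  structure(list(values = values, time_points_h = as.numeric(time_points_h)),
            class = "expression_series")
}

#' Read an expression table (TSV dialect)
#'
#' First column `gene`, remaining columns `ZT0`, `ZT3`, ... (time in hours
#' after lights-on). One row per gene; duplicate ids, ragged rows, missing
#' cells and negative values are rejected with the offending row named.
#'
#' @param path file path.
#' @return An `expression_series`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(tab) < 2L || names(tab)[1] != "gene")
    stop("expected a 'gene' column followed by ZT<h> columns in ", path)
  zt <- names(tab)[-1]
  if (!all(grepl("^ZT[0-9.]+$", zt)))
    stop("time-point columns must be named ZT<hours>, got: ",
         paste(zt[!grepl("^ZT[0-9.]+$", zt)], collapse = ", "))
  dup <- tab$gene[duplicated(tab$gene)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  bad <- tab$gene[rowSums(is.na(vals)) > 0]
  if (length(bad)) stop("missing value(s) in row(s): ", paste(bad, collapse = ", "))
  neg <- tab$gene[rowSums(vals < 0) > 0]
  if (length(neg)) stop("negative value(s) in row(s): ", paste(neg, collapse = ", "))
  rownames(vals) <- tab$gene
  expression_series(vals, as.numeric(sub("^ZT", "", zt)))
}

#' Write an expression series as TSV
#'
#' @param series an `expression_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(series, path) {
  df <- data.frame(gene = rownames(series$values), series$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalize an expression series
#'
#' Scales each gene's profile over the whole time series to `[0, 1]`:
#' `n(g,t) = (x(g,t) - min) / (max - min)`. At its lowest point a gene thus
#' blocks flux through its reaction, at its highest the flux bound is
#' saturated. Constant (zero-variance) profiles map to all-1 (a
#' constitutively saturated enzyme, not a blocked one). `method = "max"`
#' offers plain division by the per-gene maximum instead.
#'
#' @param series an `expression_series` with at least two time points.
#' @param method `"minmax"` (default) or `"max"`.
#' @return A `normalized_series`: like the input plus a `provenance`
#'   character vector ("measured" per gene present).
#' @export
normalize_expression <- function(series, method = c("minmax", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "expression_series") ||
            inherits(series, "normalized_series"))
  v <- series$values
  if (ncol(v) < 2L) stop("need at least two time points to normalize")
  out <- t(apply(v, 1L, function(x) {
    if (method == "minmax") {
      rng <- max(x) - min(x)
      if (rng == 0) rep(1, length(x)) else (x - min(x)) / rng
    } else {
      if (max(x) == 0) rep(1, length(x)) else x / max(x)
    }
  }))
  dimnames(out) <- dimnames(v)
  structure(list(values = out, time_points_h = series$time_points_h,
                 provenance = stats::setNames(
                   rep("measured", nrow(out)), rownames(out)),
                 method = method),
            class = c("normalized_series", "expression_series"))
}

#' Expression floor for genes without measured profiles
#' @keywords internal
.EXPR_FLOOR <- 0.01

#' Per-reaction activity multipliers at one time point
#'
#' For every gene-associated reaction the multiplier is the sum over its
#' genes of the normalized expression at the given time index (isozyme
#' abundances add). Genes absent from the series contribute the 0.01
#' imputation floor; `overrides` replace a gene's contribution entirely
#' (the mechanism of the deletion and impact scans). Reactions without
#' gene association (including non-transporter exchanges) get multiplier 1.
#'
#' @param norm a `normalized_series`.
#' @param model a `starch_model`.
#' @param t_index time-point index (1-based) into the series.
#' @param overrides named numeric vector, gene id -> value >= 0.
#' @return Named numeric vector of multipliers over all reactions.
#' @export
reaction_activity <- function(norm, model, t_index, overrides = NULL) {
  stopifnot(inherits(norm, "normalized_series"))
  if (!(t_index %in% seq_along(norm$time_points_h)))
    stop("t_index out of range")
  if (!is.null(overrides) && length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named vector of gene values")
    unknown <- setdiff(names(overrides), model$gene_table$orf)
    if (length(unknown))
      stop("override for unknown gene(s): ", paste(unknown, collapse = ", "))
    if (any(overrides < 0)) stop("override values must be >= 0")
  }
  gene_value <- function(g) {
    if (!is.null(overrides) && g %in% names(overrides))
      return(unname(overrides[g]))
    if (g %in% rownames(norm$values))
      return(norm$values[g, t_index])
    .EXPR_FLOOR
  }
  rx <- model$reactions
  mult <- stats::setNames(rep(1, nrow(rx)), rx$id)
  for (j in seq_len(nrow(rx))) {
    gs <- rx$gene_ids[[j]]
    if (length(gs)) mult[j] <- sum(vapply(gs, gene_value, numeric(1)))
  }
  mult
}

#' Scale reaction bounds by activity multipliers
#'
#' Returns a copy of the model in which every reaction's upper bound is
#' multiplied by its activity multiplier; lower bounds of reversible
#' reactions are scaled symmetrically (enzyme abundance limits both
#' directions). Multipliers default to 1 for reactions not named. The
#' input model is unchanged.
#'
#' @param model a `starch_model` (typically after [set_phase()]).
#' @param multipliers named numeric vector from [reaction_activity()].
#' @return The scaled model.
#' @export
apply_activity <- function(model, multipliers) {
  if (any(multipliers < 0)) stop("negative multiplier")
  unknown <- setdiff(names(multipliers), model$reactions$id)
  if (length(unknown))
    stop("multipliers for unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  m <- stats::setNames(rep(1, nrow(model$reactions)), model$reactions$id)
  m[names(multipliers)] <- multipliers
  rx <- model$reactions
  rx$upper_bound <- rx$upper_bound * m
  neg <- rx$lower_bound < 0
  rx$lower_bound[neg] <- rx$lower_bound[neg] * m[neg]
  model$reactions <- rx
  model
}

#' @export
print.expression_series <- function(x, ...) {
  cat(if (inherits(x, "normalized_series")) "Normalized" else "Raw",
      "expression series:", nrow(x$values), "genes x",
      length(x$time_points_h), "time points (h:",
      paste(x$time_points_h, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
as.data.frame.expression_series <- function(x, ...) {
  data.frame(gene = rownames(x$values), x$values,
             check.names = FALSE, stringsAsFactors = FALSE)
}
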