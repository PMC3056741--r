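# In-silico single-gene impact and deletion scans over the diel cycle.

.check_gene <- function(model, gene_id) {
  if (!(gene_id %in% model$gene_table$orf))
    stop("unknown gene '", gene_id, "'; valid ids: ",
         paste(model$gene_table$orf, collapse = ", "))
  invisible(gene_id)
}

#' Single-gene impact on the diel starch pattern
#'
#' The chosen gene follows its (normalized or floor-imputed) expression
#' profile while every other gene is pinned at maximum level (contribution
#' 1.0 to its reactions' multiplier sums), isolating how that one gene's
#' rhythm limits the flux distribution.
#'
#' @param model a `starch_model`.
#' @param norm a `normalized_series`.
#' @param schedule a `diel_schedule`.
#' @param gene_id ORF identifier.
#' @return A `diel_trajectory`.
#' @export
single_gene_impact <- function(model, norm, schedule = diel_schedule(),
                               gene_id) {
  .check_gene(model, gene_id)
  others <- setdiff(model$gene_table$orf, gene_id)
  overrides <- stats::setNames(rep(1, length(others)), others)
  simulate_cycle(model, norm, schedule, overrides = overrides)
}

#' Expression value mimicking a gene knockout
#' @keywords internal
.KO_VALUE <- 0.01

#' In-silico single-gene deletion
#'
#' The deleted gene's expression is overridden to the constant knockdown
#' value 0.01 at every time point (a marginal knockdown rather than a hard
#' zero); all other genes follow their profiles. Isozymes of the deleted
#' gene still contribute to shared reactions through the additive rule.
#'
#' @inheritParams single_gene_impact
#' @return A `diel_trajectory`.
#' @export
gene_deletion <- function(model, norm, schedule = diel_schedule(), gene_id) {
  .check_gene(model, gene_id)
  simulate_cycle(model, norm, schedule,
                 overrides = stats::setNames(.KO_VALUE, gene_id))
}

#' Deletion scan over a gene set
#'
#' Runs [gene_deletion()] for every listed gene and assembles the starch
#' and maltose exchange fluxes into gene x time matrices (the data behind
#' the 3D deletion-scan representation). Per-gene errors are recorded and
#' the scan continues.
#'
#' @param model,norm,schedule as in [single_gene_impact()].
#' @param genes character vector of ORFs (default: all model genes).
#' @return A `deletion_scan` with matrices `starch` and `maltose`
#'   (genes x time points), `times_h`, `errors`.
#' @export
deletion_scan <- function(model, norm, schedule = diel_schedule(),
                          genes = model$gene_table$orf) {
  tp <- schedule$time_points_h
  starch <- maltose <- matrix(NA_real_, nrow = length(genes),
                              ncol = length(tp),
                              dimnames = list(genes, paste0("ZT", tp)))
  errors <- character(0)
  for (g in genes) {
    tr <- tryCatch(gene_deletion(model, norm, schedule, g),
                   error = function(e) conditionMessage(e))
    if (is.character(tr)) { errors[g] <- tr; next }
    starch[g, ] <- tr$starch_flux
    maltose[g, ] <- tr$maltose_flux
  }
  structure(list(starch = starch, maltose = maltose, times_h = tp,
                 scan_kind = "deletion", errors = errors),
            class = "deletion_scan")
}

#' @export
print.deletion_scan <- function(x, ...) {
  cat("Single-gene", x$scan_kind, "scan:", nrow(x$starch), "genes x",
      length(x$times_h), "time points\n")
  if (length(x$errors))
    cat("  failed genes:", paste(names(x$errors), collapse = ", "), "\n")
  amp <- apply(x$starch, 1L, function(v) diff(range(v, na.rm = TRUE)))
  cat("  smallest remaining starch-flux amplitude:\n")
  print(utils::head(sort(amp), 5), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.deletion_scan <- function(x, ...) {
  genes <- rownames(x$starch)
  data.frame(
    gene = rep(genes, each = length(x$times_h)),
    time_h = rep(x$times_h, times = length(genes)),
    starch_flux = as.vector(t(x$starch)),
    maltose_flux = as.vector(t(x$maltose)),
    stringsAsFactors = FALSE
  )
}

#' Cut reactions of the starch-synthesis route, and their genes
#'
#' A reaction is a synthesis cut (bridge) if knocking out that single
#' reaction makes a positive starch exchange flux structurally impossible
#' (checked by maximizing the starch exchange under otherwise saturated
#' default light-phase bounds). Every carbon route from CO2 fixation to
#' the assembled granule passes through such a reaction, so genes mapped
#' to cut reactions are the topological candidates for pattern-flattening
#' deletions.
#'
#' @param model a `starch_model`.
#' @param tol flux threshold below which synthesis counts as blocked.
#' @return Character vector of ORFs mapped to at least one cut reaction.
#' @export
starch_blocking_genes <- function(model, tol = 1e-6) {
  lightm <- set_phase(model, TRUE)
  w <- stats::setNames(rep(0, nrow(lightm$reactions)), lightm$reactions$id)
  w["EX_STARCH"] <- 1
  cut <- character(0)
  for (j in seq_len(nrow(lightm$reactions))) {
    if (!length(lightm$reactions$gene_ids[[j]])) next
    m <- lightm
    m$reactions$upper_bound[j] <- 0
    m$reactions$lower_bound[j] <- 0
    up <- solve_fba(m, w, minimize_total_flux = FALSE)
    vmax <- if (up$status == "optimal") up$fluxes[["EX_STARCH"]] else 0
    if (abs(vmax) < tol) cut <- c(cut, lightm$reactions$id[j])
  }
  sort(unique(unlist(
    lightm$reactions$gene_ids[lightm$reactions$id %in% cut])))
}
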