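#' Paired volume comparison
#'
#' Paired two-sided test of pre vs post volumes (or any paired volumes),
#' defaulting to the paired t-test with a Wilcoxon signed-rank alternative.
#' A degenerate case (all pairwise differences identical, zero variance) is
#' reported with `p = 1` when the common difference is 0 and flagged via
#' `degenerate = TRUE` rather than erroring.
#'
#' @param a,b equal-length numeric vectors of paired volumes (ml), n >= 3.
#' @param method `"t"` (paired t-test) or `"wilcoxon"` (signed-rank).
#' @return List: `effect_ml` (mean of `a - b`), `p_value`, `method`,
#'   `n`, `degenerate`.
#' @export
paired_volume_test <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired samples differ in length (", length(a), " vs ", length(b), ")")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- a - b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    p <- if (all(d == 0)) 1 else 0
  } else if (method == "t") {
    p <- stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    p <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
  list(effect_ml = mean(d), p_value = p, method = method, n = length(a),
       degenerate = degenerate)
}

#' CT vs CBCT modality agreement
#'
#' Paired test plus Bland-Altman-style agreement of the same orbit measured
#' with two modalities: mean difference and 1.96 SD limits of agreement.
#'
#' @param volumes_ct,volumes_cbct paired per-case volumes (ml).
#' @param method test passed to [paired_volume_test()].
#' @return List: `mean_difference_ml`, `loa_lower_ml`, `loa_upper_ml`,
#'   `p_value`, `n`.
#' @export
modality_agreement <- function(volumes_ct, volumes_cbct, method = "t") {
  tst <- paired_volume_test(volumes_cbct, volumes_ct, method = method)
  d <- as.numeric(volumes_cbct) - as.numeric(volumes_ct)
  s <- stats::sd(d)
  list(mean_difference_ml = mean(d),
       loa_lower_ml = mean(d) - 1.96 * s,
       loa_upper_ml = mean(d) + 1.96 * s,
       p_value = tst$p_value, n = length(d))
}

#' Closed vocabularies for cohort records
#' @name cohort_vocab
#' @export
fracture_classes <- function() {
  c("anterior_central_floor", "floor_posterior_ledge",
    "complex_medial", "complex_lateral")
}

#' @rdname cohort_vocab
#' @export
treatment_groups <- function() c("Navi", "conv")

#' Assemble and validate a cohort table of case records
#'
#' @param records data.frame with columns `case_id`, `gender`
#'   (`male`/`female`), `side`, `fracture_class` (see
#'   [fracture_classes()]), `group` (`Navi`/`conv`) and volume columns
#'   `unaffected_CT`, `affected_CT`, `unaffected_CBCT`,
#'   `reconstructed_CBCT` (ml).
#' @return The validated data.frame (class `cohort_records`).
#' @export
cohort_records <- function(records) {
  need <- c("case_id", "gender", "side", "fracture_class", "group",
            "unaffected_CT", "affected_CT", "unaffected_CBCT",
            "reconstructed_CBCT")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$fracture_class %in% fracture_classes()))
    stop("unknown fracture_class value(s)")
  if (!all(records$group %in% treatment_groups()))
    stop("unknown group value(s); expected Navi/conv")
  vols <- records[, c("unaffected_CT", "affected_CT", "unaffected_CBCT",
                      "reconstructed_CBCT")]
  if (any(as.matrix(vols) <= 0, na.rm = TRUE)) stop("volumes must be positive")
  class(records) <- c("cohort_records", class(records))
  records
}

#' Stratified volume summary (mean +- SD)
#'
#' Group means and SDs of the volume columns by one or more stratifiers,
#' reproducing the layout of gender / fracture-class / treatment-group
#' volume tables. Single-record cells get `sd = 0` and `sd_flag = TRUE`;
#' empty cells appear with `n = 0`.
#'
#' @param records A [cohort_records()] table.
#' @param stratifiers character vector of stratifier column names
#'   (`gender`, `fracture_class`, `group`, `side`).
#' @param volumes which volume columns to summarise.
#' @return A long data.frame: stratifier columns, `volume`, `n`, `mean_ml`,
#'   `sd_ml`, `sd_flag`.
#' @export
group_summary <- function(records,
                          stratifiers = "gender",
                          volumes = c("unaffected_CT", "affected_CT",
                                      "unaffected_CBCT", "reconstructed_CBCT")) {
  allowed <- c("gender", "fracture_class", "group", "side")
  bad <- setdiff(stratifiers, allowed)
  if (length(bad)) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  levels_of <- function(s) switch(s,
    gender = c("male", "female"),
    fracture_class = fracture_classes(),
    group = treatment_groups(),
    side = c("right", "left"))
  grid <- expand.grid(c(lapply(stratifiers, levels_of), list(volume = volumes)),
                      stringsAsFactors = FALSE)
  names(grid) <- c(stratifiers, "volume")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, nrow(records))
    for (s in stratifiers) sel <- sel & records[[s]] == grid[[s]][i]
    v <- records[[grid$volume[i]]][sel]
    v <- v[is.finite(v)]
    n <- length(v)
    cbind(grid[i, , drop = FALSE],
          data.frame(n = n,
                     mean_ml = if (n > 0) mean(v) else NA_real_,
                     sd_ml = if (n > 1) stats::sd(v) else if (n == 1) 0 else NA_real_,
                     sd_flag = n == 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
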