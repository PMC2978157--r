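#' Re-sampling robustness of CePPIs and module identification
#'
#' Repeatedly subsamples the expression data without replacement within each
#' condition, reruns CePIN construction and module discovery, and reports the
#' fraction of full-data CePPIs recovered per condition plus the fraction of
#' the full-data exclusive modules re-identified.
#'
#' @param expr,design,pin,dag,ann Full pipeline inputs (see
#'   [run_comparison()]).
#' @param sizes Integer vector of per-condition subsample sizes (each >= 3 and
#'   at most the smaller condition size).
#' @param n_repeat Repeats per size (default 3).
#' @param seed Integer seed driving all subsampling.
#' @param reference Optional precomputed full-data `cepin_comparison`.
#' @param ... Further thresholds passed to [run_comparison()].
#' @return A tibble `size`, `repeat`, `recovery_<condA>`, `recovery_<condB>`,
#'   `identification_rate` (NA when the full data yields no exclusive module).
#' @export
resample_robustness <- function(expr, design, pin, dag, ann, sizes,
                                n_repeat = 3L, seed = 1L, reference = NULL,
                                ...) {
  if (any(sizes < 3L)) abort("subsample sizes must be >= 3 (PCC floor)")
  conds <- design_conditions(design)
  csize <- vapply(conds, function(cc)
    length(design_samples(design, cc)), integer(1))
  if (any(sizes > min(csize))) abort("subsample size exceeds a condition's sample count")
  if (is.null(ann$propagated)) ann <- propagate_annotations(ann, dag)
  run1 <- function(e, d) run_comparison(e, d, pin, dag, ann,
                                        topology = FALSE, evaluate = FALSE, ...)
  reference <- reference %||% run1(expr, design)
  ref_ceppi <- lapply(conds, function(cc) {
    ce <- cepin_edges(reference$cepins[[cc]]); edge_key(ce$u, ce$v)
  })
  names(ref_ceppi) <- conds
  ref_terms <- reference$exclusive[[conds[1]]]
  rows <- list()
  for (s in sizes) {
    for (r in seq_len(n_repeat)) {
      sub <- with_rng(derive_seed(seed, s * 1000L + r), {
        unlist(lapply(conds, function(cc)
          sample(design_samples(design, cc), s)))
      })
      d2 <- sample_design(sub,
                          setNames(design$condition, design$sample)[sub],
                          positive = design_positive(design))
      res <- run1(expr[, sub, drop = FALSE], d2)
      rec <- vapply(conds, function(cc) {
        full <- ref_ceppi[[cc]]
        if (!length(full)) return(NA_real_)
        ce <- cepin_edges(res$cepins[[cc]])
        mean(full %in% edge_key(ce$u, ce$v))
      }, numeric(1))
      ident <- if (length(ref_terms)) {
        mean(ref_terms %in% res$exclusive[[conds[1]]])
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        size = s, rep = r, recovery_a = rec[[1]], recovery_b = rec[[2]],
        identification_rate = ident)
    }
  }
  out <- bind_rows(rows)
  names(out)[3:4] <- paste0("recovery_", conds)
  out
}
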