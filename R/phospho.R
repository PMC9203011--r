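#' Elliptical PCA ranks of RyR positions
#'
#' Orders channels by their normalized elliptical radius in the principal
#' axes of the cluster: positions are centred, projected onto the
#' eigenvectors of the 2x2 position covariance, scaled by the square root
#' of the corresponding eigenvalue, and the Euclidean norm taken.
#' Monotonically shrinking the covariance ellipse selects channels in
#' increasing order of this rank, so the rank order fully determines which
#' channels an inner (small ranks) or outer (large ranks) selection picks.
#'
#' @param layout a [build_layout()] object.
#' @return numeric vector of nonnegative ranks, one per RyR (0 for a
#'   single-channel layout).
#' @export
elliptical_ranks <- function(layout) {
  stopifnot(inherits(layout, "cru_layout"))
  X <- as.matrix(layout$positions)
  if (nrow(X) == 1) return(0)
  Xc <- sweep(X, 2, colMeans(X))
  C <- stats::cov(X)
  ee <- eigen(C, symmetric = TRUE)
  sc <- sqrt(pmax(ee$values, 0))
  degen <- sc < 1e-9
  if (any(degen)) {
    warning("zero-variance principal axis; using the lattice constant as its scale")
    sc[degen] <- RYR_LATTICE_NM
  }
  P <- Xc %*% ee$vectors
  sqrt((P[, 1] / sc[1])^2 + (P[, 2] / sc[2])^2)
}

#' Select phosphorylated channels
#'
#' Spatial phosphorylation patterns over a cluster: `inner` takes the k
#' channels of smallest elliptical rank (cluster centre), `outer` the k
#' largest (periphery), `uniform` samples k channels without replacement
#' using R's RNG, `blanket` marks every channel and `none` marks none.
#' `k = round(fraction * n_ryr)`; ties in rank are broken by channel index.
#'
#' @param layout a [build_layout()] object.
#' @param pattern one of `"none"`, `"inner"`, `"outer"`, `"uniform"`,
#'   `"blanket"`.
#' @param fraction fraction of channels to phosphorylate in `[0, 1]`
#'   (ignored for `none`/`blanket`).
#' @return an object of class `phospho_assignment` with fields
#'   `pattern_kind`, `fraction`, `phosphorylated` (logical per RyR).
#' @export
select_phosphorylated <- function(layout,
                                  pattern = c("none", "inner", "outer",
                                              "uniform", "blanket"),
                                  fraction = 0) {
  stopifnot(inherits(layout, "cru_layout"))
  pattern <- match.arg(pattern)
  n <- layout$n_ryr
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round(fraction * n)
  phos <- switch(pattern,
    none = rep(FALSE, n),
    blanket = rep(TRUE, n),
    inner = {
      r <- elliptical_ranks(layout)
      seq_len(n) %in% order(r, seq_len(n))[seq_len(k)]
    },
    outer = {
      r <- elliptical_ranks(layout)
      seq_len(n) %in% order(-r, seq_len(n))[seq_len(k)]
    },
    uniform = seq_len(n) %in% sample.int(n, k)
  )
  structure(list(pattern_kind = pattern,
                 fraction = if (pattern %in% c("none", "blanket"))
                   as.numeric(pattern == "blanket") else fraction,
                 phosphorylated = phos),
            class = "phospho_assignment")
}

# calcium half-saturation of the opening rate, μM (see assign_K)
K_NONPHOS <- 55
K_PHOS_MIXED <- 25
K_BLANKET <- c(`0.2` = 45, `0.5` = 35)

#' Assign per-channel calcium sensitivities
#'
#' Maps a phosphorylation assignment to the half-saturation concentration
#' K+ of each channel's opening rate: unphosphorylated channels get 55 uM;
#' phosphorylated channels in mixed (inner/outer/uniform) patterns get
#' 25 uM; a blanket pattern sensitizes every channel mildly, with 45 uM
#' when standing in for 20% discrete phosphorylation and 35 uM when
#' standing in for 50%.
#'
#' @param assignment a [select_phosphorylated()] object.
#' @param blanket_vs for blanket patterns only: the discrete
#'   phosphorylation level being emulated, `0.2` or `0.5`.
#' @return the assignment with a `K_plus` field (uM per RyR) added.
#' @export
assign_K <- function(assignment, blanket_vs = NULL) {
  stopifnot(inherits(assignment, "phospho_assignment"))
  phos <- assignment$phosphorylated
  if (assignment$pattern_kind == "blanket") {
    if (is.null(blanket_vs) || !as.character(blanket_vs) %in% names(K_BLANKET))
      stop("blanket patterns need blanket_vs = 0.2 or 0.5 ",
           "(the discrete level being emulated)")
    K <- rep(unname(K_BLANKET[as.character(blanket_vs)]), length(phos))
  } else {
    K <- ifelse(phos, K_PHOS_MIXED, K_NONPHOS)
  }
  assignment$K_plus <- K
  assignment$blanket_vs <- if (assignment$pattern_kind == "blanket")
    as.numeric(blanket_vs) else NULL
  assignment
}

#' One-call phosphorylation assignment
#'
#' Convenience wrapper combining [select_phosphorylated()] and
#' [assign_K()].
#' @inheritParams select_phosphorylated
#' @inheritParams assign_K
#' @export
make_assignment <- function(layout, pattern = "none", fraction = 0,
                            blanket_vs = NULL) {
  assign_K(select_phosphorylated(layout, pattern, fraction), blanket_vs)
}

#' Export an assignment as CSV
#'
#' Writes `ryr_id,x_nm,y_nm,phosphorylated,K_plus_uM`.
#' @param assignment an assignment with K values ([assign_K()]).
#' @param layout the layout the assignment belongs to.
#' @param path output path.
#' @export
write_assignment_csv <- function(assignment, layout, path) {
  stopifnot(inherits(assignment, "phospho_assignment"),
            !is.null(assignment$K_plus))
  df <- data.frame(ryr_id = seq_len(layout$n_ryr),
                   x_nm = layout$positions$x_nm,
                   y_nm = layout$positions$y_nm,
                   phosphorylated = assignment$phosphorylated,
                   K_plus_uM = assignment$K_plus)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.phospho_assignment <- function(x, ...) {
  cat(sprintf("<phospho_assignment %s: %d/%d phosphorylated%s>\n",
              x$pattern_kind, sum(x$phosphorylated), length(x$phosphorylated),
              if (!is.null(x$K_plus))
                sprintf(", K+ in {%s} uM",
                        paste(sort(unique(x$K_plus)), collapse = ", "))
              else ""))
  invisible(x)
}
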