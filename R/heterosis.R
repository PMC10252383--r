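#' Mid-parent heterosis
#'
#' `MPH = 100 * (F1 - MPV) / MPV` with `MPV = (P1 + P2)/2`: the relative
#' trait gain of the hybrid over the parental mean, in percent.
#'
#' @param f1 hybrid trait value(s).
#' @param p1,p2 parental trait values (positive).
#' @return Percent MPH (vectorized).
#' @examples
#' mph(150, 100, 100)  # 50
#' @export
mph <- function(f1, p1, p2) {
  if (any(p1 <= 0 | p2 <= 0)) stop("parental values must be positive")
  mpv <- (p1 + p2) / 2
  100 * (f1 - mpv) / mpv
}

#' Better-parent heterosis
#'
#' `BPH = 100 * (F1 - BPV) / BPV` with `BPV = max(P1, P2)`: the relative
#' trait gain of the hybrid over the better parent, in percent. For a
#' positive trait `BPH <= MPH` always.
#'
#' @inheritParams mph
#' @return Percent BPH (vectorized).
#' @examples
#' bph(120, 80, 100)  # 20
#' @export
bph <- function(f1, p1, p2) {
  if (any(p1 <= 0 | p2 <= 0)) stop("parental values must be positive")
  bpv <- pmax(p1, p2)
  100 * (f1 - bpv) / bpv
}

#' Per-environment mid-parent and better-parent heterosis
#'
#' Point estimates use the genotype replicate means within each
#' environment; the spread is computed over all (hybrid, female, male)
#' replicate pairings.
#'
#' @param records data.frame with columns `genotype` (`female`, `male`,
#'   `hybrid`), `environment`, `replicate`, `value` (positive trait
#'   measurement, e.g. plant height in cm).
#' @return data.frame with one row per environment: `environment`, `mph`,
#'   `bph` (on replicate means), `mph_min`, `mph_max`, `bph_min`,
#'   `bph_max`, `n_pairings`.
#' @export
heterosis_by_environment <- function(records) {
  need <- c("genotype", "environment", "replicate", "value")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$value <= 0)) stop("trait values must be positive")
  envs <- unique(records$environment)
  rows <- lapply(envs, function(e) {
    r <- records[records$environment == e, , drop = FALSE]
    vals <- split(r$value, r$genotype)
    for (g in c("female", "male", "hybrid"))
      if (is.null(vals[[g]]) || length(vals[[g]]) == 0L)
        stop("missing genotype '", g, "' in environment ", e)
    grid <- expand.grid(f1 = vals$hybrid, p1 = vals$female, p2 = vals$male)
    m_all <- mph(grid$f1, grid$p1, grid$p2)
    b_all <- bph(grid$f1, grid$p1, grid$p2)
    data.frame(environment = e,
               mph = mph(mean(vals$hybrid), mean(vals$female), mean(vals$male)),
               bph = bph(mean(vals$hybrid), mean(vals$female), mean(vals$male)),
               mph_min = min(m_all), mph_max = max(m_all),
               bph_min = min(b_all), bph_max = max(b_all),
               n_pairings = nrow(grid), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
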