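# Three-phase segmentation of colony area-time series (exponential
# micro-colony growth, division arrest, resumed adapted growth), and a pixel
# area estimator for synthetic binary colony masks.

#' Segment a colony growth curve into three phases
#'
#' Fits a continuous piecewise-linear model with two changepoints to
#' log(area) by exhaustive search over all changepoint pairs on the
#' observation grid, minimizing the residual sum of squares; ties are broken
#' towards the earliest (t1, t2). The curve is three-phase when the fitted
#' slopes show growth / flat / growth: s1 > `s_min`, |s2| < `s_flat`,
#' s3 > `s_min`.
#'
#' @param series an `area_time_series` (or list with `t` and `area`)
#' @param min_segment_points minimum observations per segment (default 4)
#' @param s_flat phase-II slope magnitude bound, per hour on the log-area
#'   scale (default 0.005: "almost no increase")
#' @param s_min minimum growth slope for phases I and III (default 0.02)
#' @return list of class `phase_segmentation`: `changepoints` (t1, t2),
#'   `slopes` (s1, s2, s3), `sse`, `valid_three_phase`, `fitted` (log-area)
#' @export
segment_phases <- function(series, min_segment_points = 4L,
                           s_flat = 0.005, s_min = 0.02) {
  t <- series$t; area <- series$area
  n <- length(t)
  msp <- assert_count(min_segment_points, "min_segment_points", min = 2)
  if (n < 3L * msp)
    stop("series too short: need at least 3 * min_segment_points observations",
         call. = FALSE)
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing", call. = FALSE)
  if (any(area <= 0)) stop("'area' must be positive", call. = FALSE)
  la <- log(area)
  best <- list(sse = Inf)
  for (i in msp:(n - 2L * msp + 1L)) {        # t1 = t[i]
    h1 <- pmax(0, t - t[i])
    for (j in (i + msp - 1L):(n - msp + 1L)) { # t2 = t[j]
      X <- cbind(1, t, h1, pmax(0, t - t[j]))
      fit <- stats::.lm.fit(X, la)
      sse <- sum(fit$residuals^2)
      if (sse < best$sse) {
        b <- fit$coefficients
        best <- list(sse = sse, i = i, j = j,
                     slopes = c(s1 = b[2], s2 = b[2] + b[3],
                                s3 = b[2] + b[3] + b[4]),
                     fitted = la - fit$residuals)
      }
    }
  }
  s <- best$slopes
  structure(list(changepoints = c(t1 = t[best$i], t2 = t[best$j]),
                 slopes = s,
                 sse = best$sse,
                 valid_three_phase = unname(s[1] > s_min & abs(s[2]) < s_flat &
                                              s[3] > s_min),
                 fitted = best$fitted),
            class = "phase_segmentation")
}

#' Colony area from a binary mask
#'
#' Counts the pixels of the largest 4-connected foreground component,
#' ignoring detached debris.
#'
#' @param mask matrix of 0/1 (or logical)
#' @return area in pixels (0 with a warning for an empty mask)
#' @export
colony_area <- function(mask) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  m <- mask != 0
  if (!any(m)) {
    warning("empty mask: area 0")
    return(0L)
  }
  nr <- nrow(m); nc <- ncol(m)
  label <- matrix(0L, nr, nc)
  cur <- 0L
  best <- 0L
  stack <- integer(4L * nr * nc)   # a pixel can be pushed once per neighbour
  for (start in which(m & label == 0L)) {
    if (label[start] != 0L) next
    cur <- cur + 1L
    size <- 0L
    sp <- 1L; stack[1L] <- start
    while (sp > 0L) {
      idx <- stack[sp]; sp <- sp - 1L
      if (label[idx] != 0L) next
      label[idx] <- cur
      size <- size + 1L
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      if (r > 1L && m[idx - 1L] && label[idx - 1L] == 0L) {
        sp <- sp + 1L; stack[sp] <- idx - 1L }
      if (r < nr && m[idx + 1L] && label[idx + 1L] == 0L) {
        sp <- sp + 1L; stack[sp] <- idx + 1L }
      if (cc > 1L && m[idx - nr] && label[idx - nr] == 0L) {
        sp <- sp + 1L; stack[sp] <- idx - nr }
      if (cc < nc && m[idx + nr] && label[idx + nr] == 0L) {
        sp <- sp + 1L; stack[sp] <- idx + nr }
    }
    if (size > best) best <- size
  }
  best
}
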