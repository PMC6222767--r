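.switch_schemes <- c("step", "shift", "switch", "lrec")

.check_switch_spec <- function(scheme, r_off, r_on = NULL) {
  scheme <- tolower(scheme)
  if (!scheme %in% .switch_schemes) {
    rlang::abort(paste0("unknown switching scheme '", scheme, "'"),
                 class = "qmmbed_validation_error")
  }
  if (!is.numeric(r_off) || length(r_off) != 1L || r_off < 0) {
    rlang::abort("r_off must be a single non-negative length (angstrom)",
                 class = "qmmbed_validation_error")
  }
  if (scheme == "switch") {
    if (is.null(r_on)) r_on <- 0.75 * r_off
    if (r_off > 0 && (r_on <= 0 || r_on >= r_off)) {
      rlang::abort("Switch requires 0 < r_on < r_off",
                   class = "qmmbed_validation_error")
    }
  }
  list(scheme = scheme, r_off = r_off, r_on = r_on)
}

#' Switching functions for the near-field/far-field boundary
#'
#' Scaling functions S(r) in \[0, 1\] applied to MM charges near the cutoff
#' so the hybrid QM/MM electrostatic energy stays continuous as charges cross
#' it. For `r > r_off` all schemes return 0. The closed forms are
#' \describe{
#'   \item{Step}{1 for `r <= r_off` (no smoothing; a charge is either fully
#'     near-field or fully far-field)}
#'   \item{Shift}{`(1 - (r/r_off)^2)^2`}
#'   \item{Switch}{1 up to `r_on`, then
#'     `(r_off^2 - r^2)^2 (r_off^2 + 2 r^2 - 3 r_on^2) / (r_off^2 - r_on^2)^3`}
#'   \item{LREC}{`1 - (2 (1 - r/r_off)^3 - 3 (1 - r/r_off)^2 + 1)^2`, the
#'     long-range electrostatic correction smoothing}
#' }
#' Shift, Switch and LREC are continuous with S(0) = 1 and S(r_off) = 0;
#' Shift and LREC additionally have zero slope at `r_off`.
#'
#' @param r distances (angstrom), non-negative; vectorized.
#' @param scheme one of `"step"`, `"shift"`, `"switch"`, `"lrec"`.
#' @param r_off cutoff distance (angstrom).
#' @param r_on inner switching radius for `"switch"`; defaults to
#'   `0.75 * r_off`.
#' @return numeric vector of scale factors in \[0, 1\].
#' @examples
#' switch_value(5, "lrec", r_off = 10)   # 0.75
#' switch_value(5, "shift", r_off = 10)  # 0.5625
#' @export
switch_value <- function(r, scheme, r_off, r_on = NULL) {
  spec <- .check_switch_spec(scheme, r_off, r_on)
  if (any(r < 0)) {
    rlang::abort("distances must be non-negative",
                 class = "qmmbed_validation_error")
  }
  s <- numeric(length(r))
  inside <- r <= spec$r_off
  ri <- r[inside]
  s[inside] <- switch(
    spec$scheme,
    step = 1,
    shift = (1 - (ri / spec$r_off)^2)^2,
    lrec = {
      u <- 1 - ri / spec$r_off
      1 - (2 * u^3 - 3 * u^2 + 1)^2
    },
    switch = {
      ron <- spec$r_on; roff <- spec$r_off
      v <- ifelse(
        ri <= ron, 1,
        (roff^2 - ri^2)^2 * (roff^2 + 2 * ri^2 - 3 * ron^2) /
          (roff^2 - ron^2)^3
      )
      v
    }
  )
  pmin(pmax(s, 0), 1)
}

#' Partition MM charges into near and far fields
#'
#' A charge belongs to the near field if the distance to its closest QM atom
#' is at most `r_off` (the boundary itself counts as near). In `"group"`
#' mode a whole charge group is near if any of its members is, so neutral
#' molecules are never split by the cutoff; in `"atom"` mode each charge is
#' classified independently. Atom-based cutoffs are the natural companion of
#' the smooth switching schemes, group-based cutoffs of the Step scheme.
#'
#' @param mm an [mm_charges()].
#' @param qm a [qm_region()] with at least one atom.
#' @param r_off cutoff (angstrom).
#' @param mode `"atom"` or `"group"`.
#' @return A tibble of class `cutoff_partition`: the columns of `mm` plus
#'   `r_min` (distance to the closest QM atom, angstrom) and `near`
#'   (logical). Attributes `r_off` and `mode` record the rule.
#' @export
partition_charges <- function(mm, qm, r_off, mode = c("atom", "group")) {
  mode <- match.arg(mode)
  if (nrow(qm) < 1L) {
    rlang::abort("QM region must contain at least one atom",
                 class = "qmmbed_validation_error")
  }
  if (!is.numeric(r_off) || r_off < 0) {
    rlang::abort("r_off must be non-negative",
                 class = "qmmbed_validation_error")
  }
  out <- tibble::as_tibble(mm)
  out$r_min <- .min_dist_to_qm(mm, qm)
  if (mode == "atom" || nrow(out) == 0L) {
    out$near <- out$r_min <= r_off
  } else {
    out <- out |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(near = min(.data$r_min) <= r_off) |>
      dplyr::ungroup()
  }
  attr(out, "r_off") <- r_off
  attr(out, "mode") <- mode
  class(out) <- c("cutoff_partition", "mm_charges", class(tibble::tibble()))
  out
}

#' Split near-field charges under a switching function
#'
#' Each near-field charge `q` is divided exactly into a density-embedded
#' portion `q_I = S(r) q` and a multipole-embedded complement
#' `q_II = (1 - S(r)) q`; far-field charges keep their full value in the
#' `q_II`/far long-range set. The split conserves charge elementwise by
#' construction.
#'
#' @param part a [partition_charges()] result.
#' @param scheme,r_on switching scheme (see [switch_value()]); `r_off` is
#'   taken from the partition.
#' @return A tibble of class `split_charges`: `part` plus columns `S`
#'   (scale factor; 0 for far charges), `q_I` and `q_II`.
#' @export
split_charges <- function(part, scheme, r_on = NULL) {
  r_off <- attr(part, "r_off")
  out <- tibble::as_tibble(part)
  s <- numeric(nrow(out))
  if (any(out$near)) {
    s[out$near] <- switch_value(out$r_min[out$near], scheme, r_off, r_on)
  }
  out$S <- s
  out$q_I <- ifelse(out$near, out$S * out$q, 0)
  out$q_II <- ifelse(out$near, out$q - out$q_I, 0)
  attr(out, "r_off") <- r_off
  attr(out, "mode") <- attr(part, "mode")
  attr(out, "scheme") <- tolower(scheme)
  class(out) <- c("split_charges", class(tibble::tibble()))
  out
}

#' Net scaled charge of the near field
#'
#' Diagnostic sum of the scaled near-field charges `q_I`. Around an anion,
#' solvent hydrogens sit on average closer than oxygens, so smooth scaling
#' weights the positive charges more and the sum turns positive — the
#' compensation effect that makes scaled truncation outperform a hard Step
#' cutoff.
#'
#' @param split a [split_charges()] result.
#' @return net scaled near-field charge (e).
#' @export
scaled_net_charge <- function(split) {
  sum(split$q_I[split$near])
}
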