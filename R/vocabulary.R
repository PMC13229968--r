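# Token vocabulary: 24 organ tokens, a 199-value quantization grid
# (token IDs 24-222) and 5 special tokens (223-227) -- 228 IDs in total.

.SPECIALS <- c(SOS = 223L, EOS = 224L, META_OPEN = 225L, META_CLOSE = 226L,
               PAD = 227L)
.N_ORGAN <- 24L
.ORGAN_CODES <- c(shoot = 0L, internode = 1L, leaf_a = 3L, leaf_b = 4L,
                  leaf_c = 5L, petiole = 2L)

#' Build the parameter-token vocabulary
#'
#' The quantization grid is the deduplicated, ascending union of
#' * the constant set `{0, -10, 10, 90, 1, 3}` (frequent angle values and the
#'   two shoot-type labels),
#' * the 2.5-degree angle grid over `[-40, 360]` (161 points),
#' * four 10-point linearly spaced decimal grids over `[0.1, 1]`,
#'   `[0.01, 0.1]`, `[0.001, 0.01]` and `[0.0001, 0.001]` (metre-scale organ
#'   dimensions).
#'
#' With defaults this yields 199 distinct grid values mapped to token IDs
#' 24..222; organ tokens occupy 0..23 and the five special tokens
#' (SOS, EOS, META_OPEN, META_CLOSE, PAD) 223..227.
#'
#' Parameters whose natural range falls outside grid coverage can be routed
#' through an affine prescale: the value is multiplied by the factor before
#' grid lookup and divided by it on decode. The default registry rescales
#' `petiole_curvature` by 1/10 so that its Uniform(-200, -50) range maps onto
#' the angle grid; all other parameters use factor 1.
#'
#' @param constants Constant values merged into the grid.
#' @param angle_min,angle_max,angle_step Bounds and resolution of the angle
#'   grid, degrees.
#' @param decimal_ranges List of `c(low, high)` pairs, each expanded to 10
#'   evenly spaced values.
#' @param prescale Named numeric vector of per-parameter prescale factors.
#' @return An object of class `pa_vocabulary` with fields `param_grid`,
#'   `special_tokens`, `prescale`, `param_id_min`, `param_id_max`, `n_tokens`.
#' @export
build_vocabulary <- function(constants = c(0, -10, 10, 90, 1, 3),
                             angle_min = -40, angle_max = 360, angle_step = 2.5,
                             decimal_ranges = list(c(0.1, 1.0), c(0.01, 0.1),
                                                   c(0.001, 0.01), c(0.0001, 0.001)),
                             prescale = c(petiole_curvature = 0.1)) {
  grid <- c(constants,
            seq(angle_min, angle_max, by = angle_step),
            unlist(lapply(decimal_ranges, function(r)
              seq(r[1], r[2], length.out = 10))))
  grid <- sort(unique(round(grid, 12)))
  max_id <- .N_ORGAN + length(grid) - 1L
  if (max_id > min(.SPECIALS) - 1L)
    stop(sprintf("vocabulary config error: grid of %d values gives max parameter ID %d > %d",
                 length(grid), max_id, min(.SPECIALS) - 1L), call. = FALSE)
  structure(list(param_grid = grid,
                 special_tokens = .SPECIALS,
                 prescale = prescale,
                 param_id_min = .N_ORGAN,
                 param_id_max = as.integer(max_id),
                 n_tokens = as.integer(max(.SPECIALS) + 1L)),
            class = "pa_vocabulary")
}

#' @export
print.pa_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d organ tokens (0-23), %d grid values (%d-%d), %d specials (%d-%d)\n",
              .N_ORGAN, length(x$param_grid), x$param_id_min, x$param_id_max,
              length(x$special_tokens), min(x$special_tokens), max(x$special_tokens)))
  invisible(x)
}

#' Organ token ID
#'
#' An organ token encodes the branching order of the shoot the organ belongs
#' to and the organ type: `ID = branching_order * 6 + organ_code`. Organ codes
#' are 0 shoot, 1 internode, 2 petiole, 3-5 leaf slots, so the primary shoot
#' tag is token 0 ("00") and the largest organ ID is 23 ("35").
#'
#' @param branching_order Integer 0--3.
#' @param organ_code Integer 0--5.
#' @return Integer token ID in 0..23.
#' @export
organ_token <- function(branching_order, organ_code) {
  if (!all(branching_order %in% 0:3))
    stop("branching_order must be in 0..3", call. = FALSE)
  if (!all(organ_code %in% 0:5))
    stop("organ_code must be in 0..5", call. = FALSE)
  as.integer(branching_order) * 6L + as.integer(organ_code)
}

.prescale_factor <- function(vocab, param_name) {
  f <- unname(vocab$prescale[param_name])
  ifelse(is.na(f), 1, f)
}

# Vectorized nearest-grid lookup; ties broken toward the smaller grid value.
.quantize_values <- function(values, grid) {
  n <- length(grid)
  i <- findInterval(values, grid, all.inside = TRUE)
  d_lo <- values - grid[i]
  d_hi <- grid[i + 1L] - values
  idx <- ifelse(d_lo <= d_hi + 1e-12, i, i + 1L)
  idx[values <= grid[1]] <- 1L
  idx[values >= grid[n]] <- n
  as.integer(idx)
}

#' Quantize a parameter value to a token ID
#'
#' Applies the parameter's prescale factor, then maps to the nearest grid
#' value; ties are broken toward the smaller grid value. For a (prescaled)
#' value within grid coverage the quantization error is at most half the
#' local grid gap.
#'
#' @param value Finite numeric value(s).
#' @param param_name Parameter name used to look up the prescale factor.
#' @param vocab A [build_vocabulary()] object.
#' @return Integer token ID(s) in `vocab$param_id_min..vocab$param_id_max`.
#' @export
quantize_parameter <- function(value, param_name = "", vocab = build_vocabulary()) {
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("parameter value must be finite", call. = FALSE)
  f <- .prescale_factor(vocab, param_name)
  vocab$param_id_min + .quantize_values(value * f, vocab$param_grid) - 1L
}

#' Decode a parameter token ID to its value
#'
#' Inverse of [quantize_parameter()]: returns the grid value divided by the
#' parameter's prescale factor. Quantizing a decoded value returns the same
#' ID (idempotence).
#'
#' @param id Integer token ID(s) in the parameter range.
#' @param param_name Parameter name used to look up the prescale factor.
#' @param vocab A [build_vocabulary()] object.
#' @return Decoded numeric value(s).
#' @export
dequantize <- function(id, param_name = "", vocab = build_vocabulary()) {
  if (any(id < vocab$param_id_min | id > vocab$param_id_max))
    stop(sprintf("token ID outside parameter range %d..%d",
                 vocab$param_id_min, vocab$param_id_max), call. = FALSE)
  f <- .prescale_factor(vocab, param_name)
  vocab$param_grid[id - vocab$param_id_min + 1L] / f
}

#' Full token table
#'
#' One row per token ID: its kind (`organ`, `parameter` or `special`) and,
#' where applicable, the branching order / organ code or the decoded grid
#' value.
#'
#' @param vocab A [build_vocabulary()] object.
#' @return A data.frame with columns `id`, `kind`, `label`, `value`.
#' @export
vocabulary_table <- function(vocab = build_vocabulary()) {
  organ <- data.frame(id = 0:23, kind = "organ",
                      label = sprintf("%d%d", rep(0:3, each = 6), rep(0:5, 4)),
                      value = NA_real_)
  param <- data.frame(id = seq(vocab$param_id_min, vocab$param_id_max),
                      kind = "parameter",
                      label = format(vocab$param_grid, trim = TRUE),
                      value = vocab$param_grid)
  special <- data.frame(id = as.integer(vocab$special_tokens), kind = "special",
                        label = sprintf("<%s>", names(vocab$special_tokens)),
                        value = NA_real_)
  out <- rbind(organ, param, special)
  out[order(out$id), , drop = FALSE]
}
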