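# Displacing pseudoatom models along normal modes. Mode vectors are
# unit-norm over all 3N coordinates, so a displacement amplitude `a` on one
# mode moves the model by RMSD a / sqrt(N); amplitudes are unitless and the
# resulting coordinates stay in Angstrom.

#' Amplitude vector for mode displacements
#'
#' @param mode_indices Unique 1-based indices into a [compute_modes()]
#'   result (normally above `n_zero`, i.e. past the six rigid-body modes).
#' @param amplitudes Matching unitless amplitudes.
#' @return An object of class `amplitude_vector`.
#' @export
amplitude_vector <- function(mode_indices, amplitudes) {
  mode_indices <- as.integer(mode_indices)
  if (anyDuplicated(mode_indices)) stop("mode indices must be unique",
                                        call. = FALSE)
  if (length(mode_indices) != length(amplitudes))
    stop("indices and amplitudes differ in length", call. = FALSE)
  structure(list(mode_indices = mode_indices,
                 amplitudes = as.numeric(amplitudes)),
            class = "amplitude_vector")
}

#' Displace a model along normal modes
#'
#' New positions are `r_i + sum_k a_k u_{k,i}` where `u_{k,i}` is the
#' 3-vector of unit-norm mode `k` at node `i`. Weights and kernel width are
#' unchanged.
#'
#' @param model A [pseudoatom_model] with N grains.
#' @param modes A [compute_modes()] result computed from this model.
#' @param amps An [amplitude_vector].
#' @return The displaced [pseudoatom_model].
#' @export
displace_model <- function(model, modes, amps) {
  stopifnot(inherits(model, "pseudoatom_model"), inherits(modes, "mode_set"),
            inherits(amps, "amplitude_vector"))
  n <- n_pseudoatoms(model)
  if (modes$n_nodes != n)
    stop("mode set was computed for ", modes$n_nodes, " nodes, model has ",
         n, call. = FALSE)
  if (length(amps$mode_indices) == 0L) return(model)
  if (any(amps$mode_indices < 1L) || any(amps$mode_indices > ncol(modes$modes)))
    stop("mode index out of range", call. = FALSE)
  disp <- modes$modes[, amps$mode_indices, drop = FALSE] %*% amps$amplitudes
  model$positions <- model$positions + matrix(disp, ncol = 3, byrow = TRUE)
  model
}

#' Animation trajectory along one normal mode
#'
#' Frames are displaced at amplitudes linearly spaced in
#' `[-amp_max, +amp_max]`; with an odd number of frames the middle frame is
#' the input model. Export with [write_trajectory()].
#'
#' @inheritParams displace_model
#' @param mode_index 1-based mode index; indices up to `modes$n_zero` are
#'   rigid-body modes and trigger a warning.
#' @param amp_max Maximum absolute amplitude.
#' @param n_frames Number of frames (>= 2).
#' @return List of `n_frames` [pseudoatom_model] objects.
#' @export
make_trajectory <- function(model, modes, mode_index, amp_max, n_frames = 11L) {
  stopifnot(n_frames >= 2L)
  if (mode_index <= modes$n_zero)
    warning("mode ", mode_index, " is a rigid-body mode; the trajectory ",
            "will be a global translation/rotation")
  a <- seq(-amp_max, amp_max, length.out = n_frames)
  lapply(a, function(ai)
    displace_model(model, modes, amplitude_vector(mode_index, ai)))
}
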