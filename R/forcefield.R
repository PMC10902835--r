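#' Stillinger--Weber force-field parameters
#'
#' Container for the parameters of the Stillinger--Weber (SW) functional
#' form used by the coarse-grained mW water model: a short-ranged two-body
#' term plus a three-body term penalizing deviations from the preferred
#' (tetrahedral) bond angle.  Both terms vanish smoothly, in value and all
#' derivatives, at the cutoff `a_cut * sigma`.
#'
#' @param epsilon energy scale (kJ/mol), > 0
#' @param sigma length scale (Angstrom), > 0
#' @param a_cut dimensionless cutoff multiplier (> 1); interaction range is
#'   `a_cut * sigma`
#' @param A,B,p,q two-body shape constants (dimensionless)
#' @param lambda3 three-body strength (dimensionless)
#' @param gamma3 three-body decay constant (dimensionless)
#' @param cos_theta0 cosine of the preferred bond angle
#' @return an object of class `ff_params`
#' @seealso [read_ff_params()] for the versioned mW parameter file shipped
#'   with the package.
#' @export
ff_params <- function(epsilon, sigma, a_cut, A, B, p, q,
                      lambda3, gamma3, cos_theta0) {
  stopifnot(epsilon > 0, sigma > 0, a_cut > 1)
  structure(
    list(epsilon = epsilon, sigma = sigma, a_cut = a_cut,
         A = A, B = B, p = p, q = q,
         lambda3 = lambda3, gamma3 = gamma3, cos_theta0 = cos_theta0),
    class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Stillinger-Weber parameters\n")
  cat(sprintf("  epsilon %.6f kJ/mol, sigma %.4f A, cutoff %.4f A\n",
              x$epsilon, x$sigma, x$a_cut * x$sigma))
  cat(sprintf("  A %.9f  B %.10f  p %g  q %g\n", x$A, x$B, x$p, x$q))
  cat(sprintf("  lambda3 %.2f  gamma3 %.2f  cos_theta0 %.6f\n",
              x$lambda3, x$gamma3, x$cos_theta0))
  invisible(x)
}

# Pack parameters into the fixed numeric layout expected by the C++ kernels.
ff_pack <- function(params) {
  stopifnot(inherits(params, "ff_params"))
  as.numeric(c(params$epsilon, params$sigma, params$a_cut, params$A,
               params$B, params$p, params$q, params$lambda3,
               params$gamma3, params$cos_theta0))
}

#' Read force-field parameters from a flat key = value file
#'
#' The file format is plain text with one `key = value` pair per line;
#' `#` starts a comment.  Keys must match the fields of [ff_params()].
#'
#' @param path path to the parameter file; the default is the mW
#'   parameterization shipped with the package
#' @return an `ff_params` object
#' @export
read_ff_params <- function(path = system.file("extdata", "mw_sw.params",
                                              package = "cavityfluct")) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  expected <- c("epsilon", "sigma", "a_cut", "A", "B", "p", "q",
                "lambda3", "gamma3", "cos_theta0")
  unknown <- setdiff(keys, expected)
  if (length(unknown)) stop("unknown parameter key(s): ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(expected, keys)
  if (length(missing)) stop("missing parameter key(s): ",
                            paste(missing, collapse = ", "))
  v <- as.list(vals[match(expected, keys)])
  names(v) <- expected
  do.call(ff_params, v)
}

#' Solvent model specification
#'
#' The engine supports three solvents: the mW water model (`"mw"`), the
#' non-interacting ideal gas (`"ideal_gas"`, total energy identically zero)
#' and hard spheres (`"hard_sphere"`, energy zero or +Inf on overlap).  The
#' two reference solvents have exactly known cavity statistics and serve as
#' oracles for the samplers and estimators.
#'
#' @param model one of `"mw"`, `"ideal_gas"`, `"hard_sphere"`
#' @param params an [ff_params()] object (required for `"mw"`)
#' @param hs_diameter hard-sphere diameter in Angstrom (required for
#'   `"hard_sphere"`)
#' @return an object of class `solvent_model`
#' @export
solvent_model <- function(model = c("mw", "ideal_gas", "hard_sphere"),
                          params = NULL, hs_diameter = NULL) {
  model <- match.arg(model)
  if (model == "mw") {
    if (is.null(params)) params <- read_ff_params()
    stopifnot(inherits(params, "ff_params"))
  }
  if (model == "hard_sphere") {
    stopifnot(is.numeric(hs_diameter), hs_diameter > 0)
  }
  structure(list(model = model, params = params,
                 hs_diameter = if (is.null(hs_diameter)) 0 else hs_diameter),
            class = "solvent_model")
}

model_code <- function(sm) {
  switch(sm$model, ideal_gas = 0L, hard_sphere = 1L, mw = 2L)
}

model_params <- function(sm) {
  if (sm$model == "mw") ff_pack(sm$params) else numeric(10)
}

#' Two-body SW pair energy
#'
#' @param r scalar separation (Angstrom), > 0
#' @param params an [ff_params()] object
#' @return pair energy in kJ/mol; exactly 0 for `r >= a_cut * sigma`
#' @export
pair_energy <- function(r, params) {
  stopifnot(inherits(params, "ff_params"))
  if (any(r <= 0)) stop("pair separation must be positive")
  vapply(r, function(ri) cpp_pair_energy(ri, ff_pack(params)), numeric(1))
}

#' Three-body SW triplet energy
#'
#' Energy of the angular term for the triplet (j, i, k) with central
#' particle i, given the separation vectors from the center to its two
#' neighbors.  Proportional to `(cos(theta) - cos_theta0)^2` and zero when
#' either separation reaches the cutoff.
#'
#' @param r_ij,r_ik 3-vectors from the central particle to each neighbor
#'   (Angstrom); must be nonzero
#' @param params an [ff_params()] object
#' @return triplet energy in kJ/mol (non-negative)
#' @export
triplet_energy <- function(r_ij, r_ik, params) {
  stopifnot(inherits(params, "ff_params"),
            length(r_ij) == 3, length(r_ik) == 3)
  if (sum(r_ij^2) == 0 || sum(r_ik^2) == 0)
    stop("zero-length separation vector")
  cpp_triplet_energy(as.numeric(r_ij), as.numeric(r_ik), ff_pack(params))
}

#' Total potential energy of a frame
#'
#' Sum of all pair terms and all distinct ordered-center triplet terms under
#' the minimum-image convention in an orthorhombic periodic box.
#'
#' @param frame a [solvent_frame()]
#' @param model a [solvent_model()] (or an [ff_params()] object, interpreted
#'   as the mW solvent)
#' @return total energy in kJ/mol
#' @export
total_energy <- function(frame, model) {
  stopifnot(inherits(frame, "solvent_frame"))
  if (inherits(model, "ff_params")) model <- solvent_model("mw", params = model)
  cutoff <- interaction_cutoff(model)
  if (cutoff > 0 && min(frame$box_lengths) < 2 * cutoff)
    stop("box edge smaller than twice the interaction cutoff")
  cpp_total_energy(frame$positions, frame$box_lengths,
                   model_params(model), model_code(model), model$hs_diameter)
}

interaction_cutoff <- function(model) {
  switch(model$model,
         ideal_gas = 0,
         hard_sphere = model$hs_diameter,
         mw = model$params$a_cut * model$params$sigma)
}

#' Energy change for a single-particle move
#'
#' Equals `total_energy(after) - total_energy(before)` up to floating-point
#' accumulation, computed from local interactions only.
#'
#' @param frame a [solvent_frame()]
#' @param moved_index index (1-based) of the particle to move
#' @param new_position 3-vector with the trial position (Angstrom)
#' @param model a [solvent_model()] or [ff_params()]
#' @return energy difference in kJ/mol
#' @export
delta_energy <- function(frame, moved_index, new_position, model) {
  stopifnot(inherits(frame, "solvent_frame"),
            moved_index >= 1, moved_index <= nrow(frame$positions),
            length(new_position) == 3)
  if (inherits(model, "ff_params")) model <- solvent_model("mw", params = model)
  cpp_delta_energy(frame$positions, as.integer(moved_index) - 1L,
                   as.numeric(new_position), frame$box_lengths,
                   model_params(model), model_code(model), model$hs_diameter)
}
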