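#' Heligman-Pollard parameter set
#'
#' Construct the eight-parameter vector of the Heligman-Pollard (HP) law of
#' mortality.  The parameters, in the fixed order `A`...`H`, are:
#'
#' * `A` -- level of child mortality (probability scale);
#' * `B` -- location offset of the infant decline (years);
#' * `C` -- rate of decline of childhood mortality (dimensionless);
#' * `D` -- severity of the accident hump (probability scale);
#' * `E` -- concentration of the accident hump (dimensionless);
#' * `F` -- age at the accident-hump peak (years);
#' * `G` -- baseline level of senescent (Gompertz) mortality (probability
#'   scale);
#' * `H` -- rate of increase of senescent mortality (dimensionless; above 1
#'   whenever mortality rises with age).
#'
#' All parameters must be finite and non-negative.  `F` and `H` must be
#' strictly positive (they enter through logarithms and powers); the other
#' parameters may be exactly zero, in which case the corresponding term
#' vanishes.  Model fitting (see [fit_hp()]) constrains every parameter to be
#' strictly positive, so estimated parameter sets always are.
#'
#' @param A,B,C,D,E,F,G,H Numeric scalars, see Details.  Alternatively `A`
#'   may be a single numeric vector of length 8 in the order `A`...`H`.
#' @return A named numeric vector of length 8 with class `"hp_params"`.
#' @examples
#' p <- hp_params_reference()
#' hp_qx(p, 45)
#' @seealso [hp_qx()], [fit_hp()], [hp_params_reference()]
#' @export
hp_params <- function(A, B, C, D, E, F, G, H) {
  x <- if (missing(B)) as.numeric(A) else c(A, B, C, D, E, F, G, H)
  if (length(x) != 8L) {
    stop("an HP parameter set has exactly 8 values (A...H), got ", length(x))
  }
  names(x) <- hp_param_names
  validate_hp_params(x)
  structure(x, class = "hp_params")
}

hp_param_names <- c("A", "B", "C", "D", "E", "F", "G", "H")

validate_hp_params <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("HP parameters must all be finite numbers")
  }
  if (any(x < 0)) {
    stop("HP parameters must be non-negative; offending: ",
         paste(hp_param_names[x < 0], collapse = ", "))
  }
  if (x[["F"]] <= 0 || x[["H"]] <= 0) {
    stop("HP parameters F and H must be strictly positive")
  }
  invisible(x)
}

#' Reference Heligman-Pollard parameters for a cardiovascular cohort
#'
#' A fitted HP parameter set for an at-risk cardiovascular cohort observed
#' between ages 45 and 86.  On that window the senescent (Gompertz) term
#' dominates; the childhood and accident-hump terms are retained so the
#' full eight-parameter law can be evaluated at any positive age.  Used as
#' the default truth of the synthetic-data generator and as the default
#' optimisation start of [fit_hp()].
#'
#' @return An [hp_params] object.
#' @examples
#' hp_params_reference()
#' @export
hp_params_reference <- function() {
  hp_params(A = 3.2484e-04, B = 4.0001e-03, C = 2.1487e-01,
            D = 9.9836e-04, E = 1.0164e+01, F = 1.6450e+01,
            G = 2.9952e-03, H = 1.0629e+00)
}

#' @export
print.hp_params <- function(x, ...) {
  cat("Heligman-Pollard parameters:\n")
  print(format(unclass(x), digits = 5, scientific = TRUE), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hp_params <- function(x, ...) {
  as.data.frame(as.list(unclass(x)))
}

#' Read or write HP parameters as a one-row CSV
#'
#' The on-disk format is a single CSV record with header `A,B,C,D,E,F,G,H`.
#' Comment lines starting with `#` are ignored on read.
#'
#' @param path File path.
#' @param params An [hp_params] object.
#' @param comment Optional comment line (without the leading `#`) written
#'   above the header, used for provenance stamps.
#' @return `read_hp_params()` returns an [hp_params] object;
#'   `write_hp_params()` returns `path` invisibly.
#' @export
read_hp_params <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(hp_param_names %in% names(df))) {
    stop("HP parameter CSV must have columns ", paste(hp_param_names, collapse = ","))
  }
  if (nrow(df) != 1L) stop("HP parameter CSV must have exactly one row")
  hp_params(as.numeric(df[1L, hp_param_names]))
}

#' @rdname read_hp_params
#' @export
write_hp_params <- function(params, path, comment = NULL) {
  stopifnot(inherits(params, "hp_params"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(params), con, row.names = FALSE)
  invisible(path)
}
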