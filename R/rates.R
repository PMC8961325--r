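#' Kinetic rate parameters of the four-pool network
#'
#' Container for the eleven first-order rate constants of the postprandial
#' central-carbon model: seven transformation rates `k` (glycolytic entry,
#' forward/backward lactate dehydrogenase, forward/backward alanine
#' aminotransferase, citrate synthesis into the TCA cycle, protein-derived
#' alanine entry) and four lumped disposal rates `d` that absorb all
#' intracellular processes not modelled explicitly. All rates are in 1/min.
#'
#' @param k_GLY Glucose M6 -> pyruvate M3 entry rate (glycolysis).
#' @param k_LDHf,k_LDHb Pyruvate <-> lactate interconversion (LDH).
#' @param k_ALTf,k_ALTb Pyruvate <-> alanine interconversion (ALT).
#' @param k_TCA Pyruvate -> citrate rate (TCA entry).
#' @param k_Pro Protein pool -> alanine entry rate (zero when no dietary
#'   protein is ingested, as in a pure glucose intervention).
#' @param d_pyr,d_lac,d_ala,d_cit Lumped disposal rates of the four simulated
#'   pools.
#' @return An object of class `rate_params`: a named numeric vector of
#'   length 11.
#' @export
#' @examples
#' rate_params(k_GLY = 0.01, k_LDHf = 0.3, k_LDHb = 0.05, k_ALTf = 0.1,
#'             k_ALTb = 0.05, k_TCA = 0.05, k_Pro = 0, d_pyr = 0.05,
#'             d_lac = 0.05, d_ala = 0.05, d_cit = 0.05)
rate_params <- function(k_GLY, k_LDHf, k_LDHb, k_ALTf, k_ALTb, k_TCA, k_Pro,
                        d_pyr, d_lac, d_ala, d_cit) {
  x <- c(k_GLY = k_GLY, k_LDHf = k_LDHf, k_LDHb = k_LDHb, k_ALTf = k_ALTf,
         k_ALTb = k_ALTb, k_TCA = k_TCA, k_Pro = k_Pro, d_pyr = d_pyr,
         d_lac = d_lac, d_ala = d_ala, d_cit = d_cit)
  validate_rate_params(x)
  structure(x, class = "rate_params")
}

rate_names <- function() {
  c("k_GLY", "k_LDHf", "k_LDHb", "k_ALTf", "k_ALTb", "k_TCA", "k_Pro",
    "d_pyr", "d_lac", "d_ala", "d_cit")
}

validate_rate_params <- function(x) {
  if (!is.numeric(x) || length(x) != 11L || !identical(names(x), rate_names())) {
    stop("rate parameters must be the 11 named rates ",
         paste(rate_names(), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("all rates must be finite", call. = FALSE)
  if (any(x < 0)) stop("all rates must be non-negative", call. = FALSE)
  invisible(x)
}

#' Coerce a named numeric vector to `rate_params`
#'
#' @param x Named numeric vector containing all 11 rates (any order).
#' @return A `rate_params` object.
#' @export
as_rate_params <- function(x) {
  if (inherits(x, "rate_params")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || !all(rate_names() %in% names(x))) {
    stop("`x` must carry all rate names: ", paste(rate_names(), collapse = ", "),
         call. = FALSE)
  }
  x <- x[rate_names()]
  validate_rate_params(x)
  structure(x, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Kinetic rate parameters (1/min):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
as.data.frame.rate_params <- function(x, ...) {
  data.frame(parameter = names(x), value = as.numeric(x),
             stringsAsFactors = FALSE)
}

#' Read and write rate parameter sets
#'
#' Rate sets serialise to a flat two-column `parameter,value` CSV or a flat
#' JSON object keyed by the exact rate names.
#'
#' @param x A `rate_params` object.
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `read_rate_params` returns a `rate_params` object;
#'   `write_rate_params` returns `path` invisibly.
#' @export
write_rate_params <- function(x, path) {
  x <- as_rate_params(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(unclass(x)), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_rate_params
#' @export
read_rate_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    v <- stats::setNames(d$value, d$parameter)
  }
  as_rate_params(v)
}
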