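# Chemotaxonomic numerics: calibration curves, quinone molar ratios and
# profile correlations, FAME similarity, API binary matching, LOD/LOQ.

#' Construct a chemotaxonomic profile
#'
#' Per-strain measured components (respiratory quinone molar ratios, FAME
#' percentages, or binary API results) under one or more condition labels.
#' Undetected components are `NA` and displayed as `"ND"`.
#'
#' @param strain strain id.
#' @param values named numeric vector; names are `condition.component`
#'   (e.g. `aerobic.Q8`) or plain component names for single-condition
#'   profiles. `NA` marks not-determined cells.
#' @param sd optional vector of standard deviations, same names.
#' @return a `chem_profile` object.
#' @export
chem_profile <- function(strain, values, sd = NULL) {
  stopifnot(is.character(strain), length(strain) == 1L,
            is.numeric(values), !is.null(names(values)))
  if (any(values < 0, na.rm = TRUE)) stop("profile values must be >= 0")
  structure(list(strain = strain, values = values, sd = sd),
            class = "chem_profile")
}

#' @export
print.chem_profile <- function(x, ...) {
  cat("<chem_profile> ", x$strain, "\n", sep = "")
  v <- ifelse(is.na(x$values), "ND", format(round(x$values, 2)))
  print(stats::setNames(v, names(x$values)), quote = FALSE)
  invisible(x)
}

#' Fit an HPLC calibration curve
#'
#' Ordinary least squares `Y = a*x + b` on (concentration, response)
#' points; reports the coefficient of determination and, when a noise
#' estimate is supplied, the limits of detection and quantification from
#' the three-fold and ten-fold signal-to-noise rule:
#' `LOD = 3*noise_sd/a`, `LOQ = 10*noise_sd/a`.
#'
#' @param concentration concentrations (ng/mL), at least 3 distinct.
#' @param response detector responses.
#' @param noise_sd optional baseline noise standard deviation in response
#'   units.
#' @return a `calibration_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `range` (min/max concentration), `lod`, `loq` (ng/mL,
#'   `NA` without a noise estimate).
#' @export
fit_calibration <- function(concentration, response, noise_sd = NULL) {
  stopifnot(length(concentration) == length(response),
            length(concentration) >= 3L)
  if (length(unique(concentration)) < 2L)
    stop("zero concentration variance")
  fit <- stats::lm(response ~ concentration)
  a <- unname(stats::coef(fit)[2L]); b <- unname(stats::coef(fit)[1L])
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  lod <- loq <- NA_real_
  if (!is.null(noise_sd)) {
    lod <- 3 * noise_sd / a
    loq <- 10 * noise_sd / a
  }
  structure(list(slope = a, intercept = b, r_squared = r2,
                 range = range(concentration), lod = lod, loq = loq),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> Y = %g x + %g, R^2 = %.4f, range %g-%g\n",
              x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Invert a calibration curve to a sample concentration
#'
#' `x = (Y - b)/a` in ng/mL, divided by the sample `concentration_factor`
#' (the net enrichment of the extraction bookkeeping), converted to mg/L.
#' Responses mapping below the LOD are reported as `"<LOD"`; values
#' outside the linear range are flagged as extrapolated.
#'
#' @param curve a [fit_calibration()] result.
#' @param response detector response(s).
#' @param concentration_factor dimensionless enrichment factor applied by
#'   sample preparation (volume reductions), divided out.
#' @return list with `ng_ml` (instrument-scale concentration), `mg_l`
#'   (sample concentration), `below_lod`, `extrapolated`, and `display`
#'   (string, `"<LOD"` where applicable).
#' @export
invert_calibration <- function(curve, response, concentration_factor = 1) {
  x <- (response - curve$intercept) / curve$slope
  below <- !is.na(curve$lod) & x < curve$lod
  extra <- x < curve$range[1] | x > curve$range[2]
  mg_l <- (x / concentration_factor) / 1000      # ng/mL -> mg/L
  display <- ifelse(below, "<LOD", format(signif(mg_l, 4)))
  list(ng_ml = x, mg_l = mg_l, below_lod = below, extrapolated = extra,
       display = display)
}

#' Normalize amounts to a molar-ratio percent profile
#'
#' Each detected component becomes `100 * amount / total` over the
#' detected components; `NA` (not determined) components stay `NA` and do
#' not enter the total.
#'
#' @param amounts named numeric vector of molar amounts; `NA` = ND.
#' @return named percent vector summing to 100 over detected components.
#' @export
molar_ratio <- function(amounts) {
  stopifnot(is.numeric(amounts), !is.null(names(amounts)))
  det <- !is.na(amounts)
  if (!any(det) || sum(amounts[det]) <= 0)
    stop("molar_ratio undefined: no nonzero detected amount")
  out <- amounts
  out[det] <- 100 * amounts[det] / sum(amounts[det])
  out
}

#' Pearson correlation between two chemotaxonomic profiles
#'
#' Product-moment correlation over the paired mean values, in the order
#' given by `pairing` (for quinones: aerobic Q8, DMK8, MK8, then
#' anaerobic Q8, DMK8, MK8). Any `NA` (ND) in either profile, or zero
#' variance in either vector, makes the correlation undefined (`NA`),
#' matching the convention of printed tables.
#'
#' @param a,b [chem_profile()] objects.
#' @param pairing character vector of value names to pair; defaults to
#'   the names shared by both profiles, in `a`'s order.
#' @return Pearson r, or `NA` when undefined.
#' @export
profile_correlation <- function(a, b, pairing = NULL) {
  if (is.null(pairing))
    pairing <- intersect(names(a$values), names(b$values))
  if (length(pairing) < 3L) stop("need at least 3 paired cells")
  if (!all(pairing %in% names(a$values)) ||
      !all(pairing %in% names(b$values)))
    stop("pairing refers to missing components")
  x <- a$values[pairing]; y <- b$values[pairing]
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' FAME composition similarity
#'
#' Pearson correlation over the union of fatty-acid components of the two
#' profiles; a component missing from one profile is treated as 0 percent
#' (absent, not undetermined).
#'
#' @param a,b [chem_profile()] objects of FAME percentages.
#' @return Pearson r.
#' @export
fame_similarity <- function(a, b) {
  comps <- union(names(a$values), names(b$values))
  if (length(comps) < 3L) stop("fewer than 3 components")
  get0_ <- function(p) {
    v <- p$values[comps]
    v[is.na(v)] <- 0
    names(v) <- comps
    v
  }
  x <- get0_(a); y <- get0_(b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' API phenotype similarity index
#'
#' Simple matching coefficient over two equal-length vectors of test
#' results coded `+`, `-`, `V` (variable) and `ND`; `V` and `ND`
#' positions are excluded from the comparison. `method = "jaccard"`
#' ignores joint-negative tests.
#'
#' @param a,b character vectors over `{+, -, V, ND}`.
#' @param method `"simple"` (default) or `"jaccard"`.
#' @return similarity index in `[0, 1]`.
#' @export
api_similarity <- function(a, b, method = c("simple", "jaccard")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  ok <- a %in% c("+", "-") & b %in% c("+", "-")
  if (!any(ok)) stop("no comparable positions")
  a <- a[ok]; b <- b[ok]
  if (method == "simple") return(mean(a == b))
  both_pos <- a == "+" & b == "+"
  any_pos <- a == "+" | b == "+"
  if (!any(any_pos)) stop("no positive test in either vector")
  sum(both_pos) / sum(any_pos)
}

#' Read / write chemotaxonomic profiles as TSV
#'
#' TSV columns: `strain`, `condition`, `component`, `mean`, `sd`, `flag`
#' (`ND` marks not determined). Values are stored as
#' `condition.component` names in the profile; a single condition `"-"`
#' yields plain component names.
#'
#' @param path TSV file.
#' @return named list of [chem_profile()] objects.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "component", "mean")
  if (!all(need %in% names(df)))
    stop("profile TSV needs columns: ", paste(need, collapse = ", "))
  if (!"flag" %in% names(df)) df$flag <- ""
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  out <- list()
  for (s in unique(df$strain)) {
    sub <- df[df$strain == s, ]
    nm <- ifelse(sub$condition %in% c("", "-"), sub$component,
                 paste(sub$condition, sub$component, sep = "."))
    v <- ifelse(sub$flag == "ND", NA_real_, suppressWarnings(as.numeric(sub$mean)))
    sdv <- suppressWarnings(as.numeric(sub$sd))
    out[[s]] <- chem_profile(s, stats::setNames(v, nm),
                             sd = stats::setNames(sdv, nm))
  }
  out
}

#' @rdname read_profile_tsv
#' @param profiles named list of `chem_profile`s.
#' @export
write_profile_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    nm <- names(p$values)
    has_cond <- grepl(".", nm, fixed = TRUE)
    cond <- ifelse(has_cond, sub("\\..*$", "", nm), "-")
    comp <- ifelse(has_cond, sub("^[^.]*\\.", "", nm), nm)
    data.frame(strain = p$strain, condition = cond, component = comp,
               mean = ifelse(is.na(p$values), "", p$values),
               sd = if (is.null(p$sd)) "" else
                 ifelse(is.na(p$sd), "", p$sd),
               flag = ifelse(is.na(p$values), "ND", ""),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
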