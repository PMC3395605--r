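#' @useDynLib cgchaperone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames quantile
#' @importFrom utils head tail
NULL

# Residue order of the Miyazawa-Jernigan (1996) contact-energy table.
.mj_order <- c("CYS", "MET", "PHE", "ILE", "LEU", "VAL", "TRP", "TYR", "ALA",
               "GLY", "THR", "SER", "ASN", "GLN", "ASP", "GLU", "HIS", "ARG",
               "LYS", "PRO")

# Upper triangle (row-wise, including diagonal) of the MJ inter-residue
# contact energies e_ij in RT units; more negative = more attractive.
.mj_upper <- c(
  # CYS
  -5.44, -4.99, -5.80, -5.50, -5.83, -4.96, -4.95, -4.16, -3.57, -3.16,
  -3.11, -2.86, -2.59, -2.85, -2.41, -2.27, -3.60, -2.57, -1.95, -3.07,
  # MET
  -5.46, -6.56, -6.02, -6.41, -5.32, -5.55, -4.91, -3.94, -3.39,
  -3.51, -3.03, -2.95, -3.30, -2.57, -2.89, -3.98, -3.12, -2.48, -3.45,
  # PHE
  -7.26, -6.84, -7.28, -6.29, -6.16, -5.66, -4.81, -4.13,
  -4.28, -4.02, -3.75, -4.10, -3.48, -3.56, -4.77, -3.98, -3.36, -4.25,
  # ILE
  -6.54, -7.04, -6.05, -5.78, -5.25, -4.58, -3.78,
  -4.03, -3.52, -3.24, -3.67, -3.17, -3.27, -4.14, -3.63, -3.01, -3.76,
  # LEU
  -7.37, -6.48, -6.14, -5.67, -4.91, -4.16,
  -4.34, -3.92, -3.74, -4.04, -3.40, -3.59, -4.54, -4.03, -3.37, -4.20,
  # VAL
  -5.52, -5.18, -4.62, -4.04, -3.38,
  -3.46, -3.05, -2.83, -3.07, -2.48, -2.67, -3.58, -3.07, -2.49, -3.32,
  # TRP
  -5.06, -4.66, -3.82, -3.42,
  -3.22, -2.99, -3.07, -3.11, -2.84, -2.99, -3.98, -3.41, -2.69, -3.73,
  # TYR
  -4.17, -3.36, -3.01,
  -3.01, -2.78, -2.76, -2.97, -2.76, -2.79, -3.52, -3.16, -2.60, -3.19,
  # ALA
  -2.72, -2.31,
  -2.32, -2.01, -1.84, -1.89, -1.70, -1.51, -2.41, -1.83, -1.31, -2.03,
  # GLY
  -2.24,
  -2.08, -1.82, -1.74, -1.66, -1.59, -1.22, -2.15, -1.72, -1.15, -1.87,
  # THR
  -2.12, -1.96, -1.88, -1.90, -1.80, -1.74, -2.42, -1.90, -1.31, -1.90,
  # SER
  -1.67, -1.58, -1.49, -1.63, -1.48, -2.11, -1.62, -1.05, -1.57,
  # ASN
  -1.68, -1.71, -1.68, -1.51, -2.08, -1.64, -1.21, -1.53,
  # GLN
  -1.54, -1.46, -1.42, -1.98, -1.80, -1.29, -1.73,
  # ASP
  -1.21, -1.02, -2.32, -2.29, -1.68, -1.33,
  # GLU
  -0.91, -2.15, -2.27, -1.80, -1.26,
  # HIS
  -3.05, -2.16, -1.35, -2.25,
  # ARG
  -1.55, -0.59, -1.70,
  # LYS
  -0.12, -0.97,
  # PRO
  -1.75)

#' Miyazawa-Jernigan contact-energy magnitudes
#'
#' Returns the symmetric 20 x 20 matrix of inter-residue contact-energy
#' magnitudes (attractive interactions give positive weights) used to flavor
#' backbone-backbone native contacts.  Rows and columns are named by
#' three-letter residue codes.
#'
#' @return A symmetric numeric matrix with positive entries.
#' @export
mj_matrix <- function() {
  m <- matrix(0, 20, 20, dimnames = list(.mj_order, .mj_order))
  m[upper.tri(m, diag = TRUE)] <- .mj_upper
  m <- m + t(m) - diag(diag(m))
  -m  # magnitudes: attractive => positive
}

#' Flavored backbone contact weight
#'
#' Interpolates between the unflavored Go model (all weights 1) and the full
#' Miyazawa-Jernigan heterogeneity:
#' \deqn{\epsilon = 1 + \alpha\,(\epsilon_{MJ}(i,j) - \langle\epsilon_{MJ}\rangle)/\langle\epsilon_{MJ}\rangle}
#' where the mean is taken over the backbone-backbone contacts actually present
#' in the system.  The result is floored at 0.1 so no native contact becomes
#' repulsive.
#'
#' @param res_i,res_j Three-letter residue codes.
#' @param alpha Heterogeneity scale; 0 gives the plain Go model, 1 the
#'   "flavored" model.
#' @param mean_mj System mean of the MJ weights over its BB-BB contacts.
#' @param mj The MJ weight matrix, by default [mj_matrix()].
#' @param floor Lower bound for the returned weight.
#' @return Positive contact weight (dimensionless).
#' @export
mj_flavored_epsilon <- function(res_i, res_j, alpha = 1, mean_mj,
                                mj = mj_matrix(), floor = 0.1) {
  res_i <- toupper(res_i); res_j <- toupper(res_j)
  bad <- setdiff(unique(c(res_i, res_j)), rownames(mj))
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  if (missing(mean_mj) || !is.finite(mean_mj) || mean_mj <= 0)
    stop("mean_mj (system mean MJ weight) must be a positive number")
  e <- 1 + alpha * (mj[cbind(res_i, res_j)] - mean_mj) / mean_mj
  pmax(e, floor)
}
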