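# The published MobQoL-7D value sets: mean utility decrements with 95%
# confidence intervals per dimension and level, for the UK general
# population (GP, n = 504) and mobility-impaired (MI, n = 368) samples.
# Rows AC, CO, PD, IN, SE, ME, AX; columns levels 2-4 (level 1 is zero).

published_tables <- local({
  gp_dec <- rbind(
    AC = c(0.063, 0.106, 0.148),
    CO = c(0.054, 0.082, 0.121),
    PD = c(0.068, 0.111, 0.160),
    IN = c(0.033, 0.072, 0.124),
    SE = c(0.046, 0.068, 0.098),
    ME = c(0.055, 0.084, 0.119),
    AX = c(0.044, 0.073, 0.101))
  gp_lo <- rbind(
    AC = c(0.057, 0.097, 0.138),
    CO = c(0.049, 0.075, 0.112),
    PD = c(0.061, 0.102, 0.148),
    IN = c(0.030, 0.066, 0.115),
    SE = c(0.042, 0.062, 0.091),
    ME = c(0.050, 0.076, 0.110),
    AX = c(0.040, 0.067, 0.094))
  gp_hi <- rbind(
    AC = c(0.070, 0.116, 0.159),
    CO = c(0.059, 0.089, 0.130),
    PD = c(0.076, 0.122, 0.173),
    IN = c(0.037, 0.078, 0.134),
    SE = c(0.050, 0.074, 0.105),
    ME = c(0.060, 0.092, 0.129),
    AX = c(0.049, 0.079, 0.109))
  mi_dec <- rbind(
    AC = c(0.056, 0.085, 0.128),
    CO = c(0.055, 0.082, 0.123),
    PD = c(0.061, 0.099, 0.139),
    IN = c(0.038, 0.064, 0.108),
    SE = c(0.045, 0.063, 0.098),
    ME = c(0.050, 0.070, 0.110),
    AX = c(0.042, 0.064, 0.093))
  mi_lo <- rbind(
    AC = c(0.049, 0.076, 0.115),
    CO = c(0.049, 0.072, 0.109),
    PD = c(0.052, 0.088, 0.126),
    IN = c(0.033, 0.057, 0.098),
    SE = c(0.039, 0.056, 0.087),
    ME = c(0.043, 0.063, 0.098),
    AX = c(0.036, 0.056, 0.083))
  mi_hi <- rbind(
    AC = c(0.065, 0.094, 0.141),
    CO = c(0.062, 0.093, 0.138),
    PD = c(0.070, 0.111, 0.154),
    IN = c(0.044, 0.071, 0.119),
    SE = c(0.052, 0.072, 0.109),
    ME = c(0.057, 0.079, 0.122),
    AX = c(0.048, 0.072, 0.105))
  pad <- function(m) cbind(l1 = 0, m)
  list(
    GP = list(n = 504L, dec = pad(gp_dec), lo = pad(gp_lo), hi = pad(gp_hi)),
    MI = list(n = 368L, dec = pad(mi_dec), lo = pad(mi_lo), hi = pad(mi_hi))
  )
})

#' Published MobQoL-7D value sets
#'
#' Returns one of the two published value sets: `"GP"`, derived from a
#' representative UK general population sample (n = 504), or `"MI"`, derived
#' from a balanced sample of UK individuals with impaired mobility
#' (n = 368). Each carries the 21 non-zero mean utility decrements and
#' their 95% confidence bounds exactly as published (3 decimals).
#'
#' @param name `"GP"` or `"MI"`.
#' @return A `mobqol_value_set`.
#' @examples
#' gp <- published_value_set("GP")
#' state_utility(gp, "4444444")   # lowest possible GP utility, 0.129
#' @export
published_value_set <- function(name) {
  if (length(name) != 1L || !name %in% names(published_tables))
    stop("unknown value set '", paste(name, collapse = ","),
         "'; available sets: ", paste(names(published_tables), collapse = ", "),
         call. = FALSE)
  tb <- published_tables[[name]]
  new_value_set(name, tb$n, tb$dec, tb$lo, tb$hi,
                provenance = list(source = "published", sample = name))
}
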