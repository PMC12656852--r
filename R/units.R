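#' Convert enteric methane emission values between units
#'
#' Converts CH4 emission rates between grams per day (`"g_d"`), litres per
#' day (`"L_d"`) and megajoules per day (`"MJ_d"`). The conversion constants
#' are the standard ones used when assembling emission databases: 1 g CH4 =
#' 0.05565 MJ (gross energy of methane), and 22.4 L of CH4 at STP weigh
#' 16.0 g, so g/d = L/d x (16.0/22.4). Conversions compose through g/d, and
#' converting to the source unit is the identity.
#'
#' @param value numeric vector of emission values (must be non-negative;
#'   `NA` passes through).
#' @param from,to source and target units, one of `"g_d"`, `"L_d"`, `"MJ_d"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_emission(100, "g_d", "MJ_d")   # 5.565
#' convert_emission(22.4, "L_d", "g_d")   # 16
#' @export
convert_emission <- function(value, from = c("g_d", "L_d", "MJ_d"),
                             to = c("g_d", "L_d", "MJ_d")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("emission values must be non-negative")
  }
  if (from == to) return(value)
  # factors to g/d
  to_g <- c(g_d = 1, L_d = 16.0 / 22.4, MJ_d = 1 / 0.05565)
  value * to_g[[from]] / to_g[[to]]
}

# MJ per g of CH4 (gross energy of methane); used package-wide
CH4_MJ_PER_G <- 0.05565
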