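# WAG empirical amino-acid substitution model constants
# (Whelan & Goldman 2001), PAML residue order. Exchangeabilities are the
# lower triangle s(i,j), j = 1..19, i = j+1..20, column-major.

.aa_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.wag_exch_lower <- c(
  0.551571, 0.509848, 0.738998, 1.027040, 0.908598,
  1.582850, 1.416720, 0.316954, 0.193335, 0.397915,
  0.906265, 0.893496, 0.210494, 1.438550, 3.370790,
  2.121110, 0.113133, 0.240735, 2.006010, 0.635346,
  0.147304, 0.528191, 3.035500, 0.439157, 0.584665,
  2.137150, 0.186979, 0.497671, 5.351420, 0.683162,
  0.102711, 0.679489, 1.224190, 0.554413, 1.163920,
  0.381533, 0.251849, 5.429420, 0.265256, 1.543640,
  0.947198, 1.125560, 3.956290, 0.554236, 0.131528,
  3.0120100, 0.1982210, 0.0961621, 0.1950810, 3.9742300,
  2.0300600, 0.0719167, 1.0860000, 0.1962460, 0.0302949,
  0.616783, 6.174160, 0.865584, 0.930676, 0.039437,
  0.0848047, 0.4798550, 0.1037540, 0.0467304, 0.4239840,
  1.071760, 0.374866, 0.129767, 0.325711, 0.152335,
  0.0988179, 0.0213520, 0.3066740, 0.2489720, 0.1701350,
  0.3842870, 0.0740339, 0.3904820, 0.3980200, 0.1094040,
  1.407660, 0.512984, 0.717070, 0.543833, 1.002140,
  5.469470, 0.330052, 4.294110, 0.113917, 0.869489,
  3.8949000, 1.5452600, 0.0999208, 0.9333720, 1.0288700,
  0.857928, 0.215737, 0.227710, 0.301281, 0.567717,
  0.570025, 0.127395, 0.154263, 2.584430, 0.315124,
  0.0811339, 0.6823550, 0.7049390, 0.8227650, 0.1565570,
  0.1963030, 0.5887310, 0.2494100, 0.0304501, 0.0613037,
  0.373558, 0.174100, 0.049931, 0.243570, 1.341820,
  0.225833, 0.336983, 0.103604, 0.187247, 0.138190,
  0.499462, 0.890432, 0.404141, 0.679371, 0.696198,
  0.740169, 0.473307, 0.262569, 3.873440, 0.118358,
  3.1709700, 0.3238320, 4.2574600, 1.0594700, 0.0999288,
  0.319440, 1.458160, 0.212483, 0.420170, 7.821300,
  0.257555, 4.854020, 2.115170, 0.415844, 0.344739,
  0.326622, 0.665309, 0.398618, 1.800340, 0.934276,
  0.088836, 0.556896, 0.967130, 1.386980, 0.137505,
  0.133264, 0.305434, 1.190630, 0.171329, 0.493905,
  1.516120, 0.515706, 0.428437, 2.058450, 0.161444,
  0.545931, 0.171903, 1.529640, 6.454280, 0.649892,
  1.613280, 0.795384, 0.139405, 0.216046, 0.314887,
  4.378020, 0.523742, 0.786993, 0.232739, 0.110864,
  0.291148, 1.388230, 2.485390, 0.365369, 0.314730
)

.wag_freqs <- c(
  0.0866279086627909, 0.0439720043972004, 0.0390894039089404,
  0.0570451057045106, 0.0193078019307802, 0.0367281036728104,
  0.0580589058058906, 0.0832518083251808, 0.0244313024431302,
  0.0484660048466005, 0.0862090086209009, 0.0620286062028606,
  0.0195027019502702, 0.0384319038431904, 0.0457631045763105,
  0.0695179069517907, 0.0610127061012706, 0.0143859014385901,
  0.0352742035274204, 0.0708956070895607
)

#' WAG exchangeability matrix
#'
#' Symmetric 20x20 matrix of relative exchange rates of the WAG empirical
#' amino-acid model, in standard PAML residue order
#' (ARNDCQEGHILKMFPSTWYV). Diagonal is zero.
#'
#' @return numeric 20x20 symmetric matrix with residue dimnames.
#' @export
wag_exchangeabilities <- function() {
  S <- matrix(0, 20, 20, dimnames = list(.aa_order, .aa_order))
  k <- 1L
  for (j in 1:19) {
    for (i in (j + 1):20) {
      S[i, j] <- .wag_exch_lower[k]
      S[j, i] <- .wag_exch_lower[k]
      k <- k + 1L
    }
  }
  S
}

#' WAG stationary amino-acid frequencies
#'
#' @return named numeric vector of length 20 summing to 1.
#' @export
wag_frequencies <- function() {
  stats::setNames(.wag_freqs, .aa_order)
}
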