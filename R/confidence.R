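# Post-prediction confidence filters: hybridisation free energy / MFE ratio
# and the per-transcript binomial p-value.

# Internal nearest-neighbor stack table, version "internal-1".
# Pair labels are written top-strand-base then bottom-strand-base, where the
# top strand is the target read 5'->3' and the bottom strand the sRNA. The
# Watson-Crick x Watson-Crick entries are the standard Turner/Xia 37C RNA
# stack free energies (kcal/mol); stacks involving G:U wobbles use a
# simplified flat parameterisation (-1.2 with one wobble pair, -0.5 with
# two). This is an intentionally simple, fully deterministic energy model:
# it preserves the sign and ordering properties the MFE-ratio filter relies
# on, but does not reproduce RNAplex energies to the decimal.
nn_stack_table <- function() {
  p <- c("AU", "UA", "CG", "GC", "GU", "UG")
  S <- matrix(NA_real_, 6, 6, dimnames = list(p, p))
  set <- function(p1, p2, v) {
    S[p1, p2] <<- v
    rot <- function(x) paste0(substr(x, 2, 2), substr(x, 1, 1))
    S[rot(p2), rot(p1)] <<- v  # rotational symmetry of a stack
  }
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("UA", "AU", -1.33)
  set("CG", "AU", -2.11); set("CG", "UA", -2.08)
  set("GC", "AU", -2.35); set("GC", "UA", -2.24)
  set("CG", "CG", -3.26); set("CG", "GC", -2.36); set("GC", "CG", -3.42)
  set("GC", "GC", -3.26)
  for (a in p) for (b in p) {
    nw <- (a %in% c("GU", "UG")) + (b %in% c("GU", "UG"))
    if (nw > 0) S[a, b] <- if (nw == 1) -1.2 else -0.5
  }
  S
}

.energy_const <- list(init = 4.09, mismatch = 0.5, gap = 3.0)

# energy of a duplex given parallel top/bottom character vectors and states
energy_from_columns <- function(top, bottom, states) {
  S <- nn_stack_table()
  to_rna <- function(x) chartr("T", "U", x)
  e <- .energy_const$init
  n <- length(states)
  paired <- states <= 1L
  lab <- character(n)
  lab[paired] <- paste0(to_rna(top[paired]), to_rna(bottom[paired]))
  if (n > 1L) for (i in seq_len(n - 1L)) {
    if (paired[i] && paired[i + 1L]) e <- e + S[lab[i], lab[i + 1L]]
  }
  e + .energy_const$mismatch * sum(states == 2L) +
    .energy_const$gap * sum(states >= 3L)
}

#' Hybridisation free energy of a gap-free duplex
#'
#' Computes the free energy (kcal/mol) of the positionwise duplex between
#' `srna` (5'->3') and `target` (5'->3', same length; position i of the sRNA
#' pairs position L-i+1 of the target). The default backend is the bundled
#' nearest-neighbor stack table; `backend = "rnaplex"` shells out to
#' ViennaRNA's RNAplex when it is available on the PATH.
#'
#' @param srna sRNA sequence.
#' @param target target site sequence, equal length.
#' @param backend `"internal"` or `"rnaplex"`.
#' @return free energy in kcal/mol (negative = stable).
#' @export
duplex_mfe <- function(srna, target, backend = c("internal", "rnaplex")) {
  backend <- match.arg(backend)
  srna <- normalize_seq(srna); target <- normalize_seq(target)
  if (backend == "rnaplex") return(rnaplex_energy(srna, target))
  stopifnot(nchar(srna) == nchar(target))
  s <- strsplit(srna, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(s)
  bottom <- s[L:1]                      # sRNA 3'->5' under the target 5'->3'
  states <- vapply(seq_len(L), function(i) {
    pair_state_chr(bottom[i], t[i])
  }, integer(1))
  energy_from_columns(t, bottom, states)
}

pair_state_chr <- function(s, t) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  sc <- code[[s]]; tc <- code[[t]]
  if (sc + tc == 3L) return(0L)
  if ((sc == 2L && tc == 3L) || (sc == 3L && tc == 2L)) return(1L)
  2L
}

rnaplex_energy <- function(srna, target) {
  exe <- Sys.which("RNAplex")
  if (!nzchar(exe)) stop("energy backend failure: RNAplex not found on PATH")
  to_rna <- function(x) chartr("T", "U", x)
  inp <- paste0(to_rna(target), "\n", to_rna(srna), "\n")
  out <- tryCatch(system2(exe, stdout = TRUE, input = inp),
                  error = function(e) character(0))
  m <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\)", out))
  m <- unlist(m)
  if (length(m) == 0L) stop("energy backend failure: RNAplex output not parsable")
  as.numeric(gsub("[()\\s]", "", m[1L], perl = TRUE))
}

# energy of an accepted alignment, from its stored columns
alignment_energy <- function(a, backend = "internal") {
  stopifnot(inherits(a, "duplex_alignment"))
  if (backend == "rnaplex") {
    tgt <- gsub("-", "", a$target_line, fixed = TRUE)
    return(rnaplex_energy(a$srna, tgt))
  }
  top <- strsplit(a$target_line, "", fixed = TRUE)[[1]]
  bottom <- strsplit(a$srna_line, "", fixed = TRUE)[[1]]
  energy_from_columns(top, bottom, a$states)
}

#' Minimum-free-energy ratio of a predicted duplex
#'
#' The hybridisation free energy of the predicted duplex divided by that of
#' the perfectly complementary site for the same sRNA; 1.0 indicates a
#' perfect site and values fall towards 0 as the duplex degrades. Predictions
#' with a ratio below the chosen cutoff (default 0.7 in the pipeline) are
#' discarded; the boundary value is kept.
#'
#' @param a a `duplex_alignment`.
#' @param backend energy backend, see [duplex_mfe()].
#' @return ratio in (0, 1] for rule-compliant duplexes.
#' @export
mfe_ratio <- function(a, backend = "internal") {
  stopifnot(inherits(a, "duplex_alignment"))
  perfect <- duplex_mfe(a$srna, revcomp(a$srna), backend = backend)
  if (perfect == 0) stop("degenerate sRNA: perfect-site energy is zero")
  alignment_energy(a, backend = backend) / perfect
}

#' Per-transcript binomial p-value of a cleavage signal
#'
#' Probability that at least one of the `n_evaluated` candidate positions
#' tested on this transcript for one sRNA would show a degradome signal of
#' equal-or-better category by chance: `p = 1 - (1 - q_c)^n` with `q_c` the
#' fraction of the transcript's signal positions having category <= `c`.
#' Computed transcript by transcript.
#'
#' @param category category of the predicted cleavage site (0..4).
#' @param profile categorised degradation profile of the transcript.
#' @param n_evaluated number of candidate positions on this transcript tested
#'   for this sRNA after the three-stage filter (>= 1).
#' @return p-value in `[0, 1]`.
#' @export
site_pvalue <- function(category, profile, n_evaluated) {
  if (is.null(profile) || nrow(profile) == 0L)
    stop("empty degradation profile")
  stopifnot(!is.null(profile$category), n_evaluated >= 1L)
  q <- mean(profile$category <= category)
  1 - (1 - q)^n_evaluated
}
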