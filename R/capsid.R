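#' AAV capsid mass model
#'
#' An AAV capsid is an icosahedral 60-mer of the viral proteins VP1, VP2 and
#' VP3 (stoichiometry about 1:1:10), packaging up to 4.7 kb of single-stranded
#' DNA. The model carries per-subunit masses, the subunit stoichiometry, the
#' genome (payload) length and the average mass per nucleotide, from which the
#' mass of a capsid in any fill state follows.
#'
#' Defaults are anchored so that the empty 60-mer shell equals the 3740 kDa
#' empty-AAV9 calibration standard: VP1 = 82, VP2 = 66, VP3 = 60 kDa at
#' 5:5:50 gives exactly 5*82 + 5*66 + 50*60 = 3740 kDa. The per-VP masses are
#' otherwise free parameters. `mass_per_nt` defaults to the standard ssDNA
#' approximation of 330 Da per nucleotide.
#'
#' @param vp1_mass,vp2_mass,vp3_mass Subunit masses in kDa.
#' @param stoichiometry Integer vector of length 3: copies of VP1, VP2 and
#'   VP3 per capsid. Must sum to 60.
#' @param payload_length Genome length in nucleotides (0 to 4700).
#' @param mass_per_nt Average nucleotide mass in Da.
#'
#' @return An object of class `capsid_model`.
#' @export
#' @examples
#' m <- capsid_model()
#' capsid_mass(m, "empty")   # 3740 kDa shell
#' capsid_mass(m, "full")    # shell + payload
capsid_model <- function(vp1_mass = 82, vp2_mass = 66, vp3_mass = 60,
                         stoichiometry = c(5L, 5L, 50L),
                         payload_length = 3800, mass_per_nt = 330) {
  stoichiometry <- as.integer(stoichiometry)
  if (length(stoichiometry) != 3L || any(stoichiometry < 0L)) {
    stop("`stoichiometry` must be three non-negative VP1:VP2:VP3 counts",
         call. = FALSE)
  }
  if (sum(stoichiometry) != 60L) {
    stop("capsid stoichiometry must sum to 60 subunits, got ",
         sum(stoichiometry), call. = FALSE)
  }
  masses <- c(vp1_mass, vp2_mass, vp3_mass)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all VP masses must be positive and finite", call. = FALSE)
  }
  if (!is.finite(payload_length) || payload_length < 0) {
    stop("`payload_length` must be >= 0 nucleotides", call. = FALSE)
  }
  if (payload_length > 4700) {
    stop("`payload_length` exceeds the 4700 nt AAV packaging capacity",
         call. = FALSE)
  }
  if (mass_per_nt <= 0) stop("`mass_per_nt` must be positive", call. = FALSE)
  structure(
    list(vp1_mass = vp1_mass, vp2_mass = vp2_mass, vp3_mass = vp3_mass,
         stoichiometry = stoichiometry,
         payload_length = payload_length, mass_per_nt = mass_per_nt),
    class = "capsid_model"
  )
}

#' Shell mass of a capsid model
#'
#' Sum of stoichiometry times subunit masses, in kDa.
#'
#' @param model A [capsid_model()].
#' @return Shell mass in kDa.
#' @export
shell_mass <- function(model) {
  stopifnot(inherits(model, "capsid_model"))
  sum(model$stoichiometry *
        c(model$vp1_mass, model$vp2_mass, model$vp3_mass))
}

#' Payload (transgene) mass of a capsid model
#'
#' `payload_length * mass_per_nt`, converted to kDa.
#'
#' @inheritParams shell_mass
#' @return Payload mass in kDa for a single complete genome copy.
#' @export
payload_mass <- function(model) {
  stopifnot(inherits(model, "capsid_model"))
  model$payload_length * model$mass_per_nt / 1000
}

#' Mass of a capsid in a given fill state
#'
#' Returns the protein shell mass plus `fill_fraction` times the payload
#' mass. The fill fraction defaults by class: 0 (empty), 0.5 (partially
#' filled), 1 (full), 1.3 (overfull — more than one genome's worth of DNA,
#' still a single capsid).
#'
#' @param model A [capsid_model()].
#' @param fill_state One of `"empty"`, `"partial"`, `"full"`, `"overfull"`.
#' @param fill_fraction Fraction of one payload mass packaged. Must lie in
#'   \[0, 1\] except for the overfull class, where values > 1 are allowed.
#' @return Capsid mass in kDa.
#' @export
capsid_mass <- function(model, fill_state = c("empty", "partial", "full",
                                              "overfull"),
                        fill_fraction = NULL) {
  fill_state <- match.arg(fill_state)
  if (is.null(fill_fraction)) {
    fill_fraction <- switch(fill_state, empty = 0, partial = 0.5, full = 1,
                            overfull = 1.3)
  }
  if (!is.finite(fill_fraction) || fill_fraction < 0) {
    stop("`fill_fraction` must be >= 0", call. = FALSE)
  }
  if (fill_fraction > 1 && fill_state != "overfull") {
    stop("`fill_fraction` > 1 is only meaningful for the overfull class",
         call. = FALSE)
  }
  if (fill_state == "empty") fill_fraction <- 0
  shell_mass(model) + fill_fraction * payload_mass(model)
}

#' @export
print.capsid_model <- function(x, ...) {
  cat("AAV capsid model\n")
  cat(sprintf("  VP1:VP2:VP3 = %d:%d:%d at %.4g/%.4g/%.4g kDa (shell %.4g kDa)\n",
              x$stoichiometry[1], x$stoichiometry[2], x$stoichiometry[3],
              x$vp1_mass, x$vp2_mass, x$vp3_mass, shell_mass(x)))
  cat(sprintf("  payload %d nt at %.4g Da/nt (%.4g kDa)\n",
              as.integer(x$payload_length), x$mass_per_nt, payload_mass(x)))
  invisible(x)
}

# canonical class ordering used throughout
aav_classes <- c("empty", "partial", "full", "overfull")
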