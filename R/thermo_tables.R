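#' Nearest-neighbor thermodynamic parameter set
#'
#' Loads the duplex stack table shipped with the package (or a user-supplied
#' replacement in the same plain-text format): per-dinucleotide enthalpy
#' (kcal/mol), entropy (cal/(mol K)) and Gibbs free energy at 37 degC
#' (kcal/mol), plus initiation terms split by terminal base pair. The file
#' format is one `stack dH dS dG37` line per stack with `INIT_GC`/`INIT_AT`
#' rows for initiation, so the tables are inspectable and replaceable.
#'
#' @param path Optional path to an alternative parameter file.
#' @param conc_primer Oligo concentration (M) used by the Tm formula.
#' @param conc_na Monovalent cation concentration (M) for the entropic salt
#'   correction.
#' @return A list of class `"thermo_params"` with elements `dh`, `ds`, `dg`
#'   (named length-16 vectors, names = dinucleotide stacks), `init` (2x3
#'   matrix) and the two concentrations.
#' @export
thermo_params <- function(path = NULL, conc_primer = 5e-8, conc_na = 0.05) {
  stopifnot(conc_primer > 0, conc_na > 0)
  key <- if (is.null(path)) "default" else path
  tab <- .ps_env$nn_tables[[key]]
  if (is.null(tab)) {
    fp <- path %||% system.file("extdata", "nn_params.txt",
                                package = "primerscreen")
    if (!nzchar(fp) || !file.exists(fp))
      abort("nearest-neighbor parameter file not found")
    raw <- utils::read.table(fp, header = FALSE, comment.char = "#",
                             col.names = c("stack", "dh", "ds", "dg"),
                             stringsAsFactors = FALSE)
    stacks <- raw[!startsWith(raw$stack, "INIT"), ]
    init <- raw[startsWith(raw$stack, "INIT"), ]
    need <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            function(a, b) paste0(a, b)))
    if (!setequal(stacks$stack, need))
      abort("parameter file must cover all 16 dinucleotide stacks")
    if (!setequal(init$stack, c("INIT_GC", "INIT_AT")))
      abort("parameter file must contain INIT_GC and INIT_AT rows")
    ord <- match(stack_order(), stacks$stack)
    tab <- list(
      dh = stats::setNames(stacks$dh[ord], stack_order()),
      ds = stats::setNames(stacks$ds[ord], stack_order()),
      dg = stats::setNames(stacks$dg[ord], stack_order()),
      init = as.matrix(init[match(c("INIT_AT", "INIT_GC"), init$stack),
                            c("dh", "ds", "dg")])
    )
    rownames(tab$init) <- c("AT", "GC")
    if (is.null(.ps_env$nn_tables)) .ps_env$nn_tables <- list()
    .ps_env$nn_tables[[key]] <- tab
  }
  structure(c(tab, list(conc_primer = conc_primer, conc_na = conc_na)),
            class = "thermo_params")
}

# stack order matching the C kernels: index 4*first + second, A,C,G,T
stack_order <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

params_from_config <- function(config) {
  thermo_params(conc_primer = config$conc_primer, conc_na = config$conc_na)
}
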