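#' Packaged binding-site residue list
#'
#' Residue numbers lining the S1 distal ubiquitin-binding pocket of the
#' OTUD7A OTU domain (R249, W250, R251, W252, Q253, Q254, T255, Q256, Q257,
#' K259, E261, R265, E266, W267, E269, L270, L273, E304, E305, F306, H307,
#' P339, F340, F400) — the seed used to define the virtual-screening site
#' on the homology model. Use with [site_from_residues()] on a structure
#' carrying this numbering.
#'
#' @return Integer vector of residue numbers.
#' @export
otud7a_s1_residues <- function() {
  path <- system.file("extdata", "otud7a_s1_residues.txt",
                      package = "pocketscreen")
  as.integer(readLines(path))
}
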