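#' Red-minus-blue entropy-difference edge feature
#'
#' The banded lesion edge shows up at mid-range truth membership (high
#' entropy) in the red channel across the whole transition zone, while the
#' blue channel stays dark (low entropy) over most of it. Subtracting the
#' blue entropy map from the red one therefore keeps the edge-band signal
#' and cancels background skin and lesion-core responses; pixels where the
#' blue entropy exceeds the red go negative.
#'
#' @param E_R,E_B Entropy maps from [entropy_map()] for the R and B channels
#'   (matching shapes; channel tags are checked when present).
#' @return `H x W` feature matrix with attribute `stage = "Rb"`, values in
#'   `[-1, 1]`.
#' @export
rb_feature <- function(E_R, E_B) {
  tag_r <- attr(E_R, "channel"); tag_b <- attr(E_B, "channel")
  if (!is.null(tag_r) && tag_r != "R") stop("'E_R' is not a red-channel entropy map")
  if (!is.null(tag_b) && tag_b != "B") stop("'E_B' is not a blue-channel entropy map")
  if (!identical(dim(E_R), dim(E_B))) stop("entropy maps must share dimensions")
  structure(unclass(E_R) - unclass(E_B), channel = NULL, scalar = NULL,
            stage = "Rb")
}

#' Dilate the edge feature
#'
#' Grayscale dilation of the R-b feature map fills pinholes and thin dark
#' noise (hair shadows) inside the edge band before clustering. Dilation is
#' extensive, so the output dominates the input elementwise.
#'
#' @param Rb Feature matrix with stage `"Rb"` from [rb_feature()].
#' @param se Structuring element; defaults to the 5x5 disk.
#' @return Dilated feature matrix with attribute `stage = "DI"`.
#' @export
dilate_features <- function(Rb, se = struct_el("disk", 2)) {
  if (!identical(attr(Rb, "stage"), "Rb"))
    stop("'Rb' must be an undilated feature matrix (stage \"Rb\")")
  structure(dilate(Rb, se), stage = "DI")
}
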