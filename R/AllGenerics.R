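#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname gridValues
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridValues
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' @rdname maskVolumeMl
#' @export
setGeneric("maskVolumeMl", function(x) standardGeneric("maskVolumeMl"))

#' @rdname isCompatible
#' @export
setGeneric("isCompatible", function(x) standardGeneric("isCompatible"))
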