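Package: iolglare
Title: Non-Sequential Ray Tracing of Photic Phenomena in the Pseudophakic Eye
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates stray-light (dysphotopsia) phenomena in an eye after
    cataract surgery. Builds a pseudophakic schematic eye on the Liou-Brennan
    geometry with a parameterizable intraocular lens (6 or 7 mm optic; six
    edge designs), traces collimated oblique ray bundles through it with a
    non-sequential engine (Fresnel ray splitting, total internal reflection,
    mirror/absorbing/anti-reflecting edge idealizations, Lambertian or
    isotropic edge scattering), bins retinal irradiance by interaction path,
    and provides search procedures for the critical incidence angles at which
    edge-related photic images fall on the fovea.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
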