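Package: pacesim
Title: Discrete-Event Simulation of Dual-Chamber Pacemaker Timing and
    Anti-PMT Algorithms
Version: 0.1.0
Authors@R:
    person("pacesim", "developers", email = "pacesim@example.org",
           role = c("aut", "cre"))
Description: A deterministic, integer-millisecond discrete-event simulator of
    dual-chamber (DDD/DDI) pacemaker timing cycles coupled to a heart model
    with sinus arrest, complete atrioventricular block and prolonged 1:1
    retrograde ventriculoatrial conduction. Implements five manufacturer
    anti-pacemaker-mediated-tachycardia algorithms (detection, verification
    by AV-delay modulation, termination by PVARP extension or atrial pacing),
    refractory atrial sensing in DDI mode, post-refractory-sense atrial
    pacing delays (NCAP, atrial flutter response), and detection of
    repetitive nonreentrant ventriculoatrial synchrony from marker-channel
    event logs. Includes bench-protocol runners, programmable-parameter
    boundary sweeps, and a command-line interface over JSON scenario files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
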