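# service mix: annual visit rate and mean services per visit
mean_visits_per_person = 2.58
Diagnostic = 0.671
Restorative = 0.641
Preventive = 0.343
Prosthodontics = 0.257
CrownBridge = 0.097
Endodontics = 0.096
OralSurgery = 0.091
General = 0.029
Periodontics = 0.016
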