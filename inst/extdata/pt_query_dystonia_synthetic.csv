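pt,scope
Dystonia,narrow
Torticollis,narrow
Oculogyric crisis,narrow
Oromandibular dystonia,narrow
Opisthotonus,narrow
Blepharospasm,narrow
Trismus,narrow
Muscle contractions involuntary,narrow
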