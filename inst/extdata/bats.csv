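species,conservation_score,sensitivity_score
Myotis brandtii,2,1
Myotis myotis,3,1
Myotis dasycneme,3,2
Myotis nattereri,2,1
Myotis daubentonii,1,1
Myotis sp.,1,1
Vespertilio murinus,2,3
Barbastella barbastellus,3,1
Nyctalus noctula,2,3
Nyctalus leisleri,2,2
Plecotus austriacus,1,1
Plecotus auritus,2,1
Eptesicus serotinus,2,3
Eptesicus nilssoni,2,3
Pipistrellus pygmaeus,2,3
Pipistrellus pipistrellus,2,3
Pipistrellus nathusii,1,3
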