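"study_id","substrate_id","isoform_ids","route","parameter","n_subjects","dose_value","dose_basis","body_weight_kg","bsa_m2","geography","health_status","regimen","central_kind","central_value","dispersion_kind","dispersion_value","value_units"
"deferiprone_like_study01","deferiprone_like","SYNTH","oral","clearance",12,100,"total_mg","62.6508616019702","","Europe","healthy","single_dose","AM",2.12718085410481,"CV_fraction",0.281053518005086,"mL/min/kg"
"deferiprone_like_study02","deferiprone_like","SYNTH","oral","clearance",13,100,"total_mg","66.6119312834631","","Europe","healthy","single_dose","AM",2.04885482262241,"SD",0.706940384773861,"mL/min/kg"
"deferiprone_like_study03","deferiprone_like","SYNTH","oral","clearance",14,100,"total_mg","72.6806846602005","","Europe","healthy","single_dose","AM",1.56977699377032,"SD",0.719016522765873,"mL/min/kg"
"deferiprone_like_study04","deferiprone_like","SYNTH","oral","clearance",6,100,"total_mg","65.0985959229382","","Europe","healthy","single_dose","GM",1.63456691439194,"GSD",1.57446658096443,"mL/min/kg"
"deferiprone_like_study05","deferiprone_like","SYNTH","oral","clearance",13,100,"total_mg","67.7011026292696","","Europe","healthy","single_dose","AM",1.12153777812925,"SD",0.484185117498254,"mL/min/kg"
"deferiprone_like_study06","deferiprone_like","SYNTH","oral","clearance",14,100,"total_mg","60.6211964331094","","Europe","healthy","single_dose","GM",1.98524970634386,"GSD",1.74327251624136,"mL/min/kg"
"deferiprone_like_study07","deferiprone_like","SYNTH","oral","clearance",11,100,"total_mg","68.8534547605494","","Europe","healthy","single_dose","AM",1.60157577298019,"SD",0.550935116070122,"mL/min/kg"
"deferiprone_like_study08","deferiprone_like","SYNTH","oral","clearance",9,100,"total_mg","","","Europe","healthy","single_dose","AM",1.77173425828142,"SD",0.563720078194587,"mL/min/kg"
"deferiprone_like_study09","deferiprone_like","SYNTH","oral","clearance",6,100,"total_mg","61.5473346699175","","Europe","healthy","single_dose","AM",2.29116494362718,"SD",0.609816057297793,"mL/min/kg"
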