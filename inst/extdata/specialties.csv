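label,status
Medical Genetics,included
Neurosurgery,included
Pediatric Allergy and Immunology,included
Pediatric Cardiology,included
Pediatric Dermatology,included
Pediatric Endocrinology,included
Pediatric GI,included
Pediatric Liver,included
Pediatric Hematology/Oncology,included
Pediatric Nephrology,included
Pediatric Neurology,included
Pediatric Ophthalmology,included
Pediatric Orthopedics,included
Pediatric Otolaryngology,included
Pediatric Pulmonology,included
Pediatric Rheumatology,included
Pediatric Surgery,included
Pediatric Urology,included
Transplant,included
Plastic Surgery,included
Pediatric Infectious Disease,excluded
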