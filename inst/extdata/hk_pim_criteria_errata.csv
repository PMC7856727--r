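statement_id,field_name,printed_value,curated_value,rationale
IND073,atc_code,N07BC02,N02BE01,Printed code is the methadone substance code; N02BE01 is the paracetamol (acetaminophen) substance code
IND074,atc_code,A06AG01,M02AC,Printed code is the sodium phosphate enema code; M02AC is the topical salicylate-preparation class
IND075,atc_code,A06AD15,N07BC02,Printed code is the macrogol laxative code; N07BC02 is the methadone substance code
IND076,atc_code,M05BA,A06AG01,Printed code is the bisphosphonates class; A06AG01 is the sodium phosphate enema code
IND077,atc_code,N02AA59,A06AD65,Printed code is an opioid combination code; A06AD65 is the macrogol combinations code
IND073,status,INCLUDED,QUESTIONABLE,Printed in the final independent-of-diagnosis table although the printed median 3 fails the inclusion rule; also listed among the questionable candidates
IND074,status,INCLUDED,QUESTIONABLE,Printed in the final independent-of-diagnosis table although the printed median 3 fails the inclusion rule; also listed among the questionable candidates
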