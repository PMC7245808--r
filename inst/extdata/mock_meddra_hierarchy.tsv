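pt_code	pt_name	hlgt_name
PT001	Device failure	Device issues
PT002	Device malfunction	Device issues
PT003	Device use error	Medication errors, and other product use errors and issues
PT004	Device use issue	Device issues
PT005	Drug administered in wrong device	Medication errors, and other product use errors and issues
PT006	Drug administration error	Medication errors, and other product use errors and issues
PT007	Intentional device misuse	Medication errors, and other product use errors and issues
PT008	Intentional product misuse	Medication errors, and other product use errors and issues
PT009	Product use issue	Medication errors, and other product use errors and issues
PT010	Wrong device used	Medication errors, and other product use errors and issues
PT011	Wrong technique in device usage process	Medication errors, and other product use errors and issues
PT012	Wrong technique in product usage process	Medication errors, and other product use errors and issues
PT013	Medication error	Medication errors, and other product use errors and issues
PT014	Needle issue	Device issues
PT015	Headache	Headaches
PT016	Nausea	Gastrointestinal signs and symptoms
PT017	Dizziness	Neurological signs and symptoms
PT018	Hyperglycaemia	Glucose metabolism disorders
PT019	Cough	Respiratory signs and symptoms
PT020	Injection site pain	Administration site reactions
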