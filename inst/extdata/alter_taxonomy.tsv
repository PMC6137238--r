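code	display_name	group	synonyms
gp	GP	HCP	general practitioner|gps|doctor|family doctor|medical practitioner
pharmacist	pharmacist	HCP	pharmacists|chemist|community pharmacist
allergist_immunologist	allergist/immunologist	HCP	allergist|immunologist|allergy specialist|clinical immunologist
respiratory_specialist	respiratory specialist	HCP	respiratory physician|pulmonologist|lung specialist
ent_specialist	ENT specialist	HCP	ent|ear nose and throat specialist|otolaryngologist|ear nose throat specialist
practice_nurse	practice nurse	HCP	nurse|registered nurse
other_hcp	other HCP	HCP	other hcps|dermatologist|neurologist|optometrist|ophthalmologist|opthalmologist
alternative_therapist	alternative therapist	non-HCP	naturopath|homeopath|acupuncturist|alternative medicine practitioner|complementary therapist
parents_partner	parents/partner	non-HCP	parent|parents|partner|mother|father|mum|dad|husband|wife|spouse
family	family	non-HCP	sibling|siblings|brother|sister|relative|relatives|extended family
friends_colleagues	friends/colleagues	non-HCP	friend|friends|colleague|colleagues|workmate|coworker|co-worker
media	media	media_internet	tv|television|radio|newspaper|magazine|advertising|advertisement
internet	internet	media_internet	web|website|online|google|social media
own_experience	own experience	self	my own experience|personal experience|self|myself|experience
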