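vendor,vac_ms,study,field,value
abbott,468,1,pmt_detection,Yes
abbott,468,1,pmt_termination,Yes
abbott,468,1,required_changes,PMT Detection Rate <= 95 bpm
biotronik,468,1,pmt_detection,Yes
biotronik,468,1,pmt_termination,Yes
biotronik,468,1,required_changes,VA criterion to 500 ms
boston,468,1,pmt_detection,No
boston,468,1,pmt_termination,No
boston,468,1,required_changes,MTR <= 95 bpm
medtronic,468,1,pmt_detection,No
medtronic,468,1,pmt_termination,No
medtronic,468,1,required_changes,
microport,468,1,pmt_detection,Yes
microport,468,1,pmt_termination,Yes
microport,468,1,required_changes,
abbott,570,1,pmt_detection,No
abbott,570,1,pmt_termination,No
abbott,570,1,required_changes,PMT Detection Rate to 90 bpm and SAV shortening <= 90 ms
biotronik,570,1,pmt_detection,No
biotronik,570,1,pmt_termination,No
biotronik,570,1,required_changes,
boston,570,1,pmt_detection,No
boston,570,1,pmt_termination,No
boston,570,1,required_changes,MTR <= 80 bpm (non-terminated: VAC exceeded PVARP)
medtronic,570,1,pmt_detection,No
medtronic,570,1,pmt_termination,No
medtronic,570,1,required_changes,
microport,570,1,pmt_detection,No
microport,570,1,pmt_termination,No
microport,570,1,required_changes,
abbott,468,2,ar_detection,Yes
biotronik,468,2,ar_detection,Yes
boston,468,2,ar_detection,Yes
medtronic,468,2,ar_detection,Yes
microport,468,2,ar_detection,No
abbott,570,2,ar_detection,No
biotronik,570,2,ar_detection,Yes
boston,570,2,ar_detection,No
medtronic,570,2,ar_detection,No
microport,570,2,ar_detection,No
abbott,468,3,ap_delay_after_ar,No
abbott,468,3,rnrvas_occurrence,Yes
biotronik,468,3,ap_delay_after_ar,Yes (shortened PAV)
biotronik,468,3,rnrvas_occurrence,No
boston,468,3,ap_delay_after_ar,Yes (shortened PAV)
boston,468,3,rnrvas_occurrence,No
medtronic,468,3,ap_delay_after_ar,Yes (alternating PAV)
medtronic,468,3,rnrvas_occurrence,No
microport,468,3,ap_delay_after_ar,N/A
microport,468,3,rnrvas_occurrence,N/A
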