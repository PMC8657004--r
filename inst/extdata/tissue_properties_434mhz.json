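[{"tissue":"air","rho":1.2,"sigma":0,"eps_r":1,"k":null,"c":null,"omega":null,"Q":null,"active":false,"k_star":null,"omega_star":null},{"tissue":"blood","rho":1050,"sigma":null,"eps_r":null,"k":null,"c":3617,"omega":null,"Q":null,"active":false,"k_star":null,"omega_star":null},{"tissue":"bone","rho":1908,"sigma":0.09,"eps_r":13.1,"k":0.32,"c":1312,"omega":10,"Q":0.15,"active":true,"k_star":null,"omega_star":null},{"tissue":"brainstem","rho":1046,"sigma":1.05,"eps_r":55.1,"k":0.51,"c":3630,"omega":559,"Q":11.4,"active":true,"k_star":null,"omega_star":null},{"tissue":"cartilage","rho":1099,"sigma":0.6,"eps_r":45.1,"k":0.49,"c":3568,"omega":35,"Q":0.54,"active":true,"k_star":null,"omega_star":null},{"tissue":"cerebellum","rho":1045,"sigma":1.05,"eps_r":55.1,"k":0.51,"c":3653,"omega":763,"Q":15.5,"active":true,"k_star":null,"omega_star":null},{"tissue":"cerebrum","rho":1045,"sigma":0.75,"eps_r":56.8,"k":0.55,"c":3696,"omega":763,"Q":15.5,"active":true,"k_star":null,"omega_star":null},{"tissue":"fat","rho":911,"sigma":0.08,"eps_r":11.6,"k":0.21,"c":2348,"omega":32.7,"Q":0.51,"active":true,"k_star":0.5,"omega_star":255},{"tissue":"lucite","rho":1180,"sigma":0.003,"eps_r":2.6,"k":null,"c":null,"omega":null,"Q":null,"active":false,"k_star":null,"omega_star":null},{"tissue":"lung","rho":394,"sigma":0.38,"eps_r":23.6,"k":null,"c":null,"omega":null,"Q":null,"active":false,"k_star":null,"omega_star":null},{"tissue":"muscle","rho":1090,"sigma":0.8,"eps_r":56.7,"k":0.49,"c":3421,"omega":39.1,"Q":0.96,"active":true,"k_star":0.4,"omega_star":442.8},{"tissue":"optical_nerve","rho":1075,"sigma":0.46,"eps_r":35,"k":0.49,"c":3613,"omega":160,"Q":2.5,"active":true,"k_star":null,"omega_star":null},{"tissue":"sclera","rho":1032,"sigma":1.01,"eps_r":57.4,"k":0.58,"c":4200,"omega":380,"Q":5.9,"active":true,"k_star":null,"omega_star":null},{"tissue":"spinal_cord","rho":1005,"sigma":1.53,"eps_r":69,"k":0.59,"c":4047,"omega":160,"Q":2.5,"active":true,"k_star":null,"omega_star":null},{"tissue":"tumor","rho":1050,"sigma":0.89,"eps_r":59,"k":0.51,"c":3950,"omega":72.3,"Q":0,"active":true,"k_star":1.5,"omega_star":848},{"tissue":"thyroid","rho":1050,"sigma":0.89,"eps_r":61.3,"k":0.52,"c":3609,"omega":5624,"Q":87,"active":true,"k_star":null,"omega_star":null},{"tissue":"vitreous_humor","rho":1005,"sigma":1.53,"eps_r":69,"k":0.59,"c":4047,"omega":0,"Q":0,"active":true,"k_star":null,"omega_star":null},{"tissue":"water","rho":1000,"sigma":0.04,"eps_r":78,"k":null,"c":null,"omega":null,"Q":null,"active":false,"k_star":null,"omega_star":null}]
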